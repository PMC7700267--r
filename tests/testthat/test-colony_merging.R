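test_that("Delaunay graph handles degenerate candidate counts", {
  c1 <- make_candidate(1, 10, 10)
  g1 <- build_delaunay_graph(list(c1))
  expect_equal(g1$nodes, 1L)
  expect_equal(nrow(g1$edges), 0)

  c2 <- make_candidate(2, 40, 40)
  g2 <- build_delaunay_graph(list(c1, c2))
  expect_equal(nrow(g2$edges), 1)

  # triangle: all three edges
  c3 <- make_candidate(3, 10, 60)
  g3 <- build_delaunay_graph(list(c1, c2, c3))
  expect_equal(nrow(g3$edges), 3)

  # collinear centroids: complete-graph fallback
  cl <- lapply(1:4, function(i) make_candidate(i, 10 * i, 10 * i))
  gl <- build_delaunay_graph(cl)
  expect_equal(nrow(gl$edges), choose(4, 2))
})

test_that("Delaunay edges equal the empty-circumcircle oracle on random sets", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- sample(4:8, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    cands <- lapply(seq_len(n), function(i) {
      cd <- make_candidate(i, 0, 0)
      cd$centroid <- c(row = pts[i, 1], col = pts[i, 2])
      cd
    })
    g <- build_delaunay_graph(cands)
    expect_equal(edge_key(g$edges), edge_key(oracle_delaunay_edges(pts)),
                 info = paste("seed", seed))
  }
})

test_that("edges are pruned by distance and any-channel colour difference", {
  res <- 1.5
  # two nodes 100 um apart with small colour difference: kept
  a <- make_candidate(1, 0, 0, colour = c(100, 100, 100))
  b <- make_candidate(2, 0, 100 * res, colour = c(110, 110, 110))
  # third node 200 um away: pruned by distance
  c3 <- make_candidate(3, 0, 300 * res, colour = c(100, 100, 100))
  g <- build_delaunay_graph(list(a, b, c3))
  g <- prune_edges(g, list(a, b, c3), 105, 0.15, res)
  surv <- phytodetect:::surviving_edges(g)
  expect_equal(edge_key(surv), edge_key(matrix(c(1, 2), 1)))

  # colour difference (0, 40, 0) exceeds 38.25 on one channel: pruned
  b2 <- make_candidate(2, 0, 100 * res, colour = c(100, 140, 100))
  g2 <- build_delaunay_graph(list(a, b2))
  g2 <- prune_edges(g2, list(a, b2), 105, 0.15, res)
  expect_equal(nrow(phytodetect:::surviving_edges(g2)), 0)
  # ... but survives under the euclidean rule (40 < 38.25 * sqrt(3))
  g3 <- build_delaunay_graph(list(a, b2))
  g3 <- prune_edges(g3, list(a, b2), 105, 0.15, res, colour_rule = "euclidean")
  expect_equal(nrow(phytodetect:::surviving_edges(g3)), 1)

  # zero distance threshold prunes every edge between distinct centroids
  g4 <- prune_edges(build_delaunay_graph(list(a, b)), list(a, b), 0, 0.15, res)
  expect_equal(nrow(phytodetect:::surviving_edges(g4)), 0)
})

test_that("fusing components unions masks, bboxes and conserves pixel mass", {
  a <- make_candidate(1, 10, 10, size = 10)   # bbox (10,10,20,20)
  b <- make_candidate(2, 30, 30, size = 10)   # bbox (30,30,40,40)
  g <- build_delaunay_graph(list(a, b))
  # no surviving edges -> identity
  g0 <- prune_edges(g, list(a, b), 0, 0.15, 1.5)
  out0 <- fuse_components(g0, list(a, b))
  expect_length(out0, 2)
  expect_equal(out0[[1]]$bbox, a$bbox)

  # surviving edge -> fused bbox is the coordinate union
  g1 <- prune_edges(g, list(a, b), 1e6, 0.9, 1.5)
  out1 <- fuse_components(g1, list(a, b))
  expect_length(out1, 1)
  expect_equal(out1[[1]]$bbox, bbox(10, 10, 40, 40))
  expect_equal(out1[[1]]$area_px, a$area_px + b$area_px)
  expect_equal(sum(out1[[1]]$mask), 200)
  expect_equal(unname(out1[[1]]$centroid), c(24.5, 24.5))

  expect_equal(merge_colonies(list()), list())
})

test_that("with infinite thresholds fusion equals raw Delaunay components", {
  set.seed(42)
  for (trial in 1:5) {
    n <- sample(5:9, 1)
    cands <- lapply(seq_len(n), function(i)
      make_candidate(i, runif(1, 0, 200), runif(1, 0, 200),
                     colour = runif(3, 0, 255)))
    g <- build_delaunay_graph(cands)
    gp <- prune_edges(g, cands, Inf, 0.999, 1.5)
    out <- fuse_components(gp, cands)
    comp <- oracle_components(n, g$edges)
    expect_equal(length(out), length(unique(comp)))
    # total pixel mass conserved
    expect_equal(sum(vapply(out, function(cd) cd$area_px, numeric(1))),
                 sum(vapply(cands, function(cd) cd$area_px, numeric(1))))
  }
})

test_that("merging is invariant to candidate ordering", {
  set.seed(7)
  cands <- lapply(1:6, function(i)
    make_candidate(i, runif(1, 0, 150), runif(1, 0, 150),
                   colour = c(100, 100, 100)))
  cfg <- pipeline_config()
  out1 <- merge_colonies(cands, cfg, resolution = 1.5)
  perm <- sample(6)
  cands2 <- cands[perm]
  for (i in seq_along(cands2)) cands2[[i]]$id <- i
  out2 <- merge_colonies(cands2, cfg, resolution = 1.5)
  boxes1 <- t(vapply(out1, function(cd) unclass(cd$bbox), numeric(4)))
  boxes2 <- t(vapply(out2, function(cd) unclass(cd$bbox), numeric(4)))
  expect_equal(boxes1[order(boxes1[, 1], boxes1[, 2]), ],
               boxes2[order(boxes2[, 1], boxes2[, 2]), ])
})

test_that("planted colonies fuse to one candidate, contrasting neighbours stay apart", {
  sc <- generate_scene(quick_spec(seed = 12), "fix12")
  cfg <- pipeline_config()
  cands <- detect_candidates(sc$image, cfg)
  merged <- merge_colonies(cands, cfg, resolution = sc$image$resolution)
  det <- candidates_to_df(merged, "fix12", 1.5)
  truth <- sc$truth
  # each truth object is matched by exactly one merged candidate
  mr <- match_detections(det, truth)
  hits <- vapply(mr$det_of_gt, length, integer(1))
  expect_true(all(hits == 1))
  # and no merged candidate spans two truth objects
  expect_true(all(vapply(mr$gt_of_det, length, integer(1)) <= 1))
})
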