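# Colony merging.
#
# Sparse specimens and colonies (Volvox, Eudorina, Microcystis...) are
# detected as several disconnected candidates because the bonds between
# cells are invisible at 10x. A Delaunay triangulation of candidate
# centroids links each detection to its nearby neighbours; edges failing a
# spatial-distance or colour-similarity test are pruned, and the surviving
# connected subgraphs are fused into single candidates.

orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# signed in-circumcircle test: TRUE if d is strictly inside the circle
# through a, b, c (any orientation)
in_circumcircle <- function(a, b, c, d) {
  m <- rbind(c(a - d, sum((a - d)^2)),
             c(b - d, sum((b - d)^2)),
             c(c - d, sum((c - d)^2)))
  det(m) * sign(orient2d(a, b, c)) > 0
}

# Bowyer-Watson incremental Delaunay triangulation. Returns the unique
# undirected edge pairs (indices into `pts`). Collinear point sets have no
# triangulation; callers handle that case.
#
# The three bounding "super" vertices are treated symbolically as points at
# infinity: an in-circumcircle test against a triangle that uses a super
# vertex degenerates to a half-plane (orientation) test, so the result does
# not depend on how large the bounding triangle is drawn. With a finite
# bounding triangle, near-collinear hull triangles have circumcircles that
# reach the super vertices and the triangulation silently loses hull edges.
bowyer_watson_edges <- function(pts) {
  n <- nrow(pts)
  mins <- apply(pts, 2, min); maxs <- apply(pts, 2, max)
  d <- max(maxs - mins, 1)
  mid <- (mins + maxs) / 2
  P <- rbind(pts,
             mid + c(-30 * d, -10 * d),
             mid + c(30 * d, -10 * d),
             mid + c(0, 30 * d))
  # TRUE if finite point p (index i) lies inside the circumcircle of
  # triangle t, with super vertices (> n) at infinity
  tri_circum_contains <- function(t, i) {
    sup <- t[t > n]; fin <- t[t <= n]
    p <- P[i, ]
    if (length(sup) == 0L)
      return(in_circumcircle(P[t[1], ], P[t[2], ], P[t[3], ], p))
    if (length(sup) == 1L) {
      # half-plane bounded by the finite edge, on the super vertex's side
      a <- P[fin[1], ]; b <- P[fin[2], ]
      return(orient2d(a, b, p) * orient2d(a, b, P[sup[1], ]) > 0)
    }
    if (length(sup) == 2L) {
      # half-plane through the finite vertex, parallel to the infinite
      # direction, on the side of the super vertices
      a <- P[fin[1], ]
      dir <- P[sup[2], ] - P[sup[1], ]
      return(orient2d(a, a + dir, p) * orient2d(a, a + dir, P[sup[1], ]) > 0)
    }
    TRUE  # initial all-super triangle contains every finite point
  }
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    bad <- which(vapply(tris, tri_circum_contains, logical(1), i = i))
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad]
    for (j in seq_len(nrow(boundary)))
      tris[[length(tris) + 1L]] <- c(boundary[j, ], i)
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  if (!any(keep)) return(matrix(integer(0), 0, 2))
  e <- do.call(rbind, lapply(tris[keep], function(t)
    rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
  unique(e)
}

all_collinear <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(TRUE)
  for (k in 3:n)
    if (abs(orient2d(pts[1, ], pts[2, ], pts[k, ])) > 1e-9) return(FALSE)
  TRUE
}

#' Build the Delaunay graph over candidate centroids
#'
#' Nodes are candidate ids; edges are the Delaunay edges of the centroid
#' set. Degenerate inputs fall back gracefully: 0 or 1 candidates give no
#' edges, 2 candidates give the single pair, and fully collinear centroid
#' sets give the complete graph (so the pruning thresholds still govern
#' merging). Duplicate centroids are jittered by 1e-6 px under `seed`.
#'
#' @param cands List of candidates (see [trace_components()]).
#' @param seed Seed for the duplicate-centroid jitter.
#' @return A `candidate_graph`: nodes, centroids, `edges` and (initially
#'   empty) `pruned` edge matrices.
#' @export
build_delaunay_graph <- function(cands, seed = 1L) {
  ids <- vapply(cands, function(cd) cd$id, integer(1))
  pts <- do.call(rbind, lapply(cands, function(cd) unname(cd$centroid)))
  n <- length(cands)
  if (n >= 2L && anyDuplicated(round(pts, 9))) {
    dup <- duplicated(round(pts, 9))
    pts[dup, ] <- pts[dup, ] +
      with_seed(seed, matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2))
  }
  edges <- if (n < 2L) matrix(integer(0), 0, 2)
    else if (n == 2L) matrix(1:2, 1, 2)
    else if (all_collinear(pts)) t(utils::combn(n, 2))
    else bowyer_watson_edges(pts)
  if (nrow(edges))
    edges <- matrix(ids[edges], ncol = 2)   # back to candidate ids
  structure(list(nodes = ids, centroids = pts, edges = edges,
                 pruned = matrix(integer(0), 0, 2)),
            class = "candidate_graph")
}

#' Prune Delaunay edges by distance and colour similarity
#'
#' An edge survives iff the Euclidean centroid distance is at most
#' `distance_um` (converted to pixels) AND the candidates' mean colours
#' (average RGB over the filled segmentation mask, so background does not
#' skew the estimate) differ by at most `colour_frac * 255` — on every
#' channel for the default per-channel rule, or in RGB Euclidean distance
#' against `colour_frac * 255 * sqrt(3)` for `colour_rule = "euclidean"`.
#'
#' @param graph A `candidate_graph` from [build_delaunay_graph()].
#' @param cands The candidates the graph was built from.
#' @param distance_um Distance threshold in micrometres.
#' @param colour_frac Colour threshold as a fraction of the dynamic range.
#' @param resolution Pixels per micrometre.
#' @param colour_rule `"per_channel"` or `"euclidean"`.
#' @return The graph with failing edges moved to `$pruned`.
#' @export
prune_edges <- function(graph, cands, distance_um, colour_frac, resolution,
                        colour_rule = c("per_channel", "euclidean")) {
  colour_rule <- match.arg(colour_rule)
  if (!nrow(graph$edges)) return(graph)
  dist_px <- um_to_px(distance_um, resolution)
  cmax <- colour_frac * 255
  by_id <- match(graph$edges, graph$nodes)
  dim(by_id) <- dim(graph$edges)
  cent <- graph$centroids
  cols <- do.call(rbind, lapply(cands, function(cd) cd$mean_rgb))
  keep <- logical(nrow(graph$edges))
  for (e in seq_len(nrow(graph$edges))) {
    i <- by_id[e, 1]; j <- by_id[e, 2]
    dd <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    dc <- abs(cols[i, ] - cols[j, ])
    colour_ok <- if (colour_rule == "per_channel") all(dc <= cmax)
                 else sqrt(sum(dc^2)) <= cmax * sqrt(3)
    keep[e] <- dd <= dist_px && colour_ok
  }
  graph$pruned <- graph$edges[!keep, , drop = FALSE]
  graph
}

surviving_edges <- function(graph) {
  if (!nrow(graph$pruned)) return(graph$edges)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  graph$edges[!(key(graph$edges) %in% key(graph$pruned)), , drop = FALSE]
}

# Combine a set of member candidates into one. Members have pairwise
# disjoint masks, so area, centroid and mean colour combine exactly by
# area weighting; the fused mask is the union placed in the union bbox.
combine_candidates <- function(members) {
  if (length(members) == 1L) return(members[[1L]])
  bb <- Reduce(bbox_union, lapply(members, function(cd) cd$bbox))
  H <- bb[["y_max"]] - bb[["y_min"]]; W <- bb[["x_max"]] - bb[["x_min"]]
  mask <- matrix(FALSE, H, W)
  for (cd in members) {
    r0 <- cd$bbox[["y_min"]] - bb[["y_min"]]
    c0 <- cd$bbox[["x_min"]] - bb[["x_min"]]
    rows <- r0 + seq_len(nrow(cd$mask)); cols <- c0 + seq_len(ncol(cd$mask))
    mask[rows, cols] <- mask[rows, cols] | cd$mask
  }
  areas <- vapply(members, function(cd) cd$area_px, numeric(1))
  cent <- do.call(rbind, lapply(members, function(cd) unname(cd$centroid)))
  rgb <- do.call(rbind, lapply(members, function(cd) cd$mean_rgb))
  w <- areas / sum(areas)
  structure(list(
    id = min(vapply(members, function(cd) cd$id, integer(1))),
    contour = do.call(rbind, lapply(members, function(cd) cd$contour)),
    mask = mask,
    bbox = bb,
    centroid = c(row = sum(w * cent[, 1]), col = sum(w * cent[, 2])),
    area_px = sum(areas),
    mean_rgb = as.numeric(colSums(w * rgb))), class = "candidate")
}

#' Fuse surviving connected subgraphs into single candidates
#'
#' One output candidate per connected component of the graph restricted to
#' its surviving (unpruned) edges. Singleton components pass through
#' unchanged; fused candidates get the union mask and bbox with centroid,
#' area and mean colour recomputed.
#'
#' @param graph A pruned `candidate_graph`.
#' @param cands The candidates the graph was built from.
#' @return List of candidates, one per connected component.
#' @export
fuse_components <- function(graph, cands) {
  if (!length(cands)) return(list())
  ids <- graph$nodes
  surv <- surviving_edges(graph)
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  if (nrow(surv))
    g <- igraph::add_edges(g, as.vector(t(matrix(match(surv, ids),
                                                 ncol = 2))))
  memb <- igraph::components(g)$membership
  lapply(unique(memb), function(m) combine_candidates(cands[memb == m]))
}

#' Merge oversegmented colonies and sparse specimens
#'
#' Composes [build_delaunay_graph()], [prune_edges()] and
#' [fuse_components()], then reassigns ids in raster order of the resulting
#' bounding boxes. The triangulation is built and fused once (no iterative
#' re-triangulation).
#'
#' @param cands List of candidates with mean colours attached.
#' @param config A [pipeline_config()].
#' @param resolution Pixels per micrometre (defaults to the configured
#'   value; pass the image's own resolution if it differs).
#' @param verbose Emit a per-stage log line?
#' @param image_id Identifier used in logging.
#' @return List of merged candidates.
#' @export
merge_colonies <- function(cands, config = pipeline_config(),
                           resolution = config$resolution_px_per_um,
                           verbose = FALSE, image_id = "image") {
  if (!length(cands)) return(list())
  graph <- build_delaunay_graph(cands, seed = config$rng_seed)
  graph <- prune_edges(graph, cands, config$merge_distance_um,
                       config$merge_colour_frac, resolution,
                       config$colour_rule)
  merged <- fuse_components(graph, cands)
  ord <- order(vapply(merged, function(cd) cd$bbox[["y_min"]], numeric(1)),
               vapply(merged, function(cd) cd$bbox[["x_min"]], numeric(1)))
  merged <- merged[ord]
  for (i in seq_along(merged)) merged[[i]]$id <- i
  if (verbose)
    stage_log("merge", image_id, before = length(cands), after = length(merged))
  merged
}
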