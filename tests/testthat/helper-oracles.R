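# Independent oracles, deliberately brute-force and separate from the
# implementation paths they check.

# Gaussian-weighted local mean by direct windowed summation at every pixel,
# with symmetric (edge-inclusive) reflection — matches the package's border
# convention but none of its FFT machinery.
oracle_local_mean <- function(mat, sigma_px) {
  r <- ceiling(3 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px); k <- k / sum(k)
  H <- nrow(mat); W <- ncol(mat)
  reflect <- function(i, n) {
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  out <- matrix(0, H, W)
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    acc <- 0
    for (dr in -r:r) for (dc in -r:r) {
      acc <- acc + k[dr + r + 1] * k[dc + r + 1] *
        mat[reflect(rr + dr, H), reflect(cc + dc, W)]
    }
    out[rr, cc] <- acc
  }
  out
}

# Flood-fill labelling oracle by iterative min-label propagation: holes are
# filled by propagating border reachability through the 4-connected
# background, then 8-connected components are labelled by repeatedly taking
# the minimum label over each pixel's neighbourhood until a fixed point.
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- intersect(seq_len(H), seq_len(H) - dr)
  cs <- intersect(seq_len(W), seq_len(W) - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

oracle_label_filled <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  outside <- matrix(FALSE, H, W)
  outside[1, ] <- bg[1, ]; outside[H, ] <- bg[H, ]
  outside[, 1] <- bg[, 1]; outside[, W] <- bg[, W]
  repeat {
    grown <- (outside |
      shift_mat(outside, 1, 0, FALSE) | shift_mat(outside, -1, 0, FALSE) |
      shift_mat(outside, 0, 1, FALSE) | shift_mat(outside, 0, -1, FALSE)) & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  filled <- mask | !outside
  lab <- matrix(seq_len(H * W), H, W)
  lab[!filled] <- Inf
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) nb <- pmin(nb, shift_mat(lab, dr, dc, Inf))
    nb[!filled] <- Inf
    upd <- pmin(lab, nb)
    if (identical(upd, lab)) break
    lab <- upd
  }
  out <- matrix(0L, H, W)
  vals <- lab[filled]
  out[filled] <- match(vals, sort(unique(vals)))
  out
}

# Delaunay edge set by empty-circumcircle enumeration over all triples
# (general-position point sets).
oracle_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (n == 2) return(matrix(1:2, 1, 2))
  circum <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
    c(ux, uy)
  }
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ctr <- circum(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(ctr)) next
    rad2 <- sum((pts[i, ] - ctr)^2)
    empty <- TRUE
    for (q in seq_len(n)) {
      if (q %in% c(i, j, k)) next
      if (sum((pts[q, ] - ctr)^2) < rad2 - 1e-9) { empty <- FALSE; break }
    }
    if (empty) edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_key <- function(e) {
  if (!nrow(e)) return(character(0))
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# All-threshold brute-force precision/recall scan.
oracle_pr_points <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(th, function(t) {
    sel <- scores >= t
    data.frame(threshold = t,
               precision = sum(labels[sel] == 1) / sum(sel),
               recall = sum(labels[sel] == 1) / sum(labels == 1))
  }))
}

oracle_best_threshold <- function(scores, labels, target) {
  pts <- oracle_pr_points(scores, labels)
  ok <- pts[pts$recall >= target, ]
  ok <- ok[order(-ok$precision, -ok$threshold), ]
  ok[1, ]
}

# Union-find connected components over an edge list.
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

random_mask <- function(seed, H = 64, W = 64, p = 0.35) {
  set.seed(seed)
  m <- matrix(runif(H * W) < p, H, W)
  m
}

# small, quick scene for unit tests
quick_spec <- function(seed = 1L, ...) {
  scene_spec(width = 256L, height = 192L, n_blobs = c(2L, 2L),
             n_colonies = c(1L, 1L), n_debris = c(1L, 1L),
             edge_touch_prob = 0, seed = seed, ...)
}

# synthetic candidate for graph/merging unit tests
make_candidate <- function(id, row, col, size = 4L, colour = c(100, 100, 100)) {
  structure(list(
    id = as.integer(id),
    contour = cbind(row, col),
    mask = matrix(TRUE, size, size),
    bbox = bbox(col, row, col + size, row + size),
    centroid = c(row = row + (size - 1) / 2, col = col + (size - 1) / 2),
    area_px = size^2,
    mean_rgb = as.numeric(colour)), class = "candidate")
}
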