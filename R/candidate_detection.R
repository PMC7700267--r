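# Candidate detection: connected foreground blobs become preliminary
# specimen candidates. Internal holes are filled (the external contour
# delimits the whole candidate), then blobs that are too small to be
# taxonomically identifiable (< 5 um^2 at the default) or that touch the
# image border (partial specimens) are discarded.

# Label connected components of a logical mask. Foreground uses
# 8-connectivity so diagonal chains of cells stay one blob; the complement
# (for hole filling) uses 4-connectivity. Labels are assigned in
# column-major order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  pix <- matrix(0L, H, W)
  pix[idx] <- seq_len(n)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    if (H <= dr || W <= abs(dc)) next
    r1 <- seq_len(H - dr); c1 <- if (dc >= 0L) seq_len(W - dc) else (1L - dc):W
    r2 <- r1 + dr; c2 <- c1 + dc
    both <- mask[r1, c1, drop = FALSE] & mask[r2, c2, drop = FALSE]
    w <- which(both, arr.ind = TRUE)
    if (nrow(w)) {
      a <- pix[cbind(r1[w[, 1L]], c1[w[, 2L]])]
      b <- pix[cbind(r2[w[, 1L]], c2[w[, 2L]])]
      edges <- c(edges, rbind(a, b))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # renumber in order of first appearance (pixel column-major order)
  lab[idx] <- match(memb, memb[!duplicated(memb)])
  lab
}

# Fill internal holes: background regions (4-connected) not reachable from
# the image border become foreground.
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  bg <- !mask
  lab <- label_components(bg, connectivity = 4L)
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border_labels <- setdiff(border_labels, 0L)
  holes <- bg & !(lab %in% border_labels)
  mask | matrix(holes, nrow(mask), ncol(mask))
}

# Moore-neighbour tracing of the external contour of one component,
# clockwise, with Jacob's stopping criterion. `comp` is a logical matrix in
# which exactly one 8-connected component is TRUE.
trace_external_contour <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- comp
  # clockwise Moore neighbourhood starting north
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  w <- which(pad, arr.ind = TRUE)
  start <- w[order(w[, 1L], w[, 2L])[1L], ]           # topmost, then leftmost
  # one tracing step: from (cur, back) find the next boundary pixel by
  # scanning the Moore neighbourhood clockwise from the backtrack position
  step <- function(cur, back) {
    rel <- back - cur
    i0 <- which(dirs[, 1L] == rel[1L] & dirs[, 2L] == rel[2L])
    prev <- back
    for (j in seq_len(8L)) {
      nb <- cur + dirs[((i0 - 1L + j) %% 8L) + 1L, ]
      if (pad[nb[1L], nb[2L]]) return(list(cur = nb, back = prev))
      prev <- nb
    }
    NULL                                               # isolated pixel
  }
  cur <- start
  back <- start + c(0L, -1L)                          # west neighbour is bg
  path <- list(start)
  s1 <- step(cur, back)
  if (!is.null(s1)) {
    second <- s1$cur
    st <- s1
    seen <- new.env(hash = TRUE)
    repeat {
      if (all(st$cur == start)) {
        ahead <- step(st$cur, st$back)
        if (all(ahead$cur == second)) break            # full loop completed
      }
      key <- paste(st$cur[1L], st$cur[2L], st$back[1L], st$back[2L])
      if (!is.null(seen[[key]])) break                 # state cycle closed
      seen[[key]] <- TRUE
      path[[length(path) + 1L]] <- st$cur
      st <- step(st$cur, st$back)
    }
  }
  do.call(rbind, path) - 1L                            # drop padding offset
}

# Assemble a candidate object from a labelled component.
new_candidate <- function(id, rows, cols, lab, label_value, image = NULL) {
  rmin <- min(rows); rmax <- max(rows); cmin <- min(cols); cmax <- max(cols)
  local <- lab[rmin:rmax, cmin:cmax, drop = FALSE] == label_value
  contour <- trace_external_contour(local)             # 1-based, bbox-local
  contour <- contour + matrix(c(rmin - 2L, cmin - 2L), nrow(contour), 2L,
                              byrow = TRUE)            # 0-based full-image
  mean_rgb <- rep(NA_real_, 3L)
  if (!is.null(image)) {
    sel <- which(local, arr.ind = TRUE)
    px_r <- rmin - 1L + sel[, 1L]; px_c <- cmin - 1L + sel[, 2L]
    mean_rgb <- vapply(1:3, function(ch)
      mean(image$pixels[cbind(px_r, px_c, ch)]), numeric(1))
  }
  structure(list(
    id = as.integer(id),
    contour = contour,
    mask = local,
    bbox = bbox(cmin - 1L, rmin - 1L, cmax, rmax),     # 0-based half-open
    centroid = c(row = mean(rows) - 1, col = mean(cols) - 1),
    area_px = sum(local),
    mean_rgb = mean_rgb), class = "candidate")
}

#' Trace connected foreground components into candidates
#'
#' Fills internal holes, labels 8-connected components, and returns one
#' candidate per component with its external contour, filled mask, bounding
#' box, centroid and area. When `image` is supplied the mean RGB colour over
#' the filled mask is attached (used later for colony merging).
#'
#' @param mask Logical `H x W` foreground mask.
#' @param image Optional [microscopy_image()] the mask came from.
#' @return List of `candidate` objects (possibly empty).
#' @export
trace_components <- function(mask, image = NULL) {
  filled <- fill_holes(mask)
  lab <- label_components(filled, connectivity = 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  w <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lv == k
    out[[k]] <- new_candidate(k, w[sel, 1L], w[sel, 2L], lab, k, image)
  }
  out
}

#' Filter candidates by physical area and border contact
#'
#' Retains candidates whose filled area is at least `min_area_um2` square
#' micrometres and whose mask touches no pixel of the 1-pixel outer frame of
#' the image. Partial specimens on the border are discarded by the standard
#' counting convention; tiny blobs are too inconspicuous for taxonomic use.
#' Order is preserved; candidates are not mutated.
#'
#' @param cands List of candidates from [trace_components()].
#' @param min_area_um2 Minimum filled area in square micrometres.
#' @param image_shape `c(H, W)` of the source image in pixels.
#' @param resolution Pixels per micrometre.
#' @return Subsequence of `cands`.
#' @export
filter_candidates <- function(cands, min_area_um2, image_shape, resolution) {
  min_px <- um2_to_px2(min_area_um2, resolution)
  keep <- vapply(cands, function(cd) {
    if (cd$area_px < min_px) return(FALSE)
    b <- cd$bbox
    if (b[["y_min"]] > 0 && b[["x_min"]] > 0 &&
        b[["y_max"]] < image_shape[1] && b[["x_max"]] < image_shape[2])
      return(TRUE)
    # bbox reaches the frame: discard only if mask pixels actually touch it
    H <- image_shape[1]; W <- image_shape[2]
    rows <- b[["y_min"]] + seq_len(nrow(cd$mask)) - 1L   # 0-based
    cols <- b[["x_min"]] + seq_len(ncol(cd$mask)) - 1L
    on_frame <- outer(rows %in% c(0L, H - 1L), rep(TRUE, length(cols))) |
                outer(rep(TRUE, length(rows)), cols %in% c(0L, W - 1L))
    !any(cd$mask & on_frame)
  }, logical(1))
  cands[keep]
}

#' Detect specimen candidates in a microscopy image
#'
#' Composes [segment_foreground()], [trace_components()] and
#' [filter_candidates()]. Ids are reassigned in raster order of each
#' candidate's bounding-box top-left corner.
#'
#' @param image A [microscopy_image()].
#' @param config A [pipeline_config()].
#' @param verbose Emit a per-stage log line?
#' @return List of `candidate` objects.
#' @export
detect_candidates <- function(image, config = pipeline_config(), verbose = FALSE) {
  mask <- segment_foreground(image, config)
  cands <- trace_components(mask, image)
  n_raw <- length(cands)
  cands <- filter_candidates(cands, config$min_area_um2, dim(mask),
                             image$resolution)
  ord <- order(vapply(cands, function(cd) cd$bbox[["y_min"]], numeric(1)),
               vapply(cands, function(cd) cd$bbox[["x_min"]], numeric(1)))
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$id <- i
  if (verbose)
    stage_log("detect", image$image_id, raw = n_raw, kept = length(cands))
  cands
}

#' Tabulate candidates for export
#'
#' @param cands List of candidates.
#' @param image_id Identifier recorded in the table.
#' @param resolution Pixels per micrometre (for the `area_um2` column).
#' @return Data frame, one row per candidate.
#' @export
candidates_to_df <- function(cands, image_id = "image", resolution = 1.5) {
  if (!length(cands))
    return(data.frame(image_id = character(), id = integer(),
                      x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer(),
                      area_px = numeric(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      mean_r = numeric(), mean_g = numeric(), mean_b = numeric()))
  do.call(rbind, lapply(cands, function(cd) data.frame(
    image_id = image_id, id = cd$id,
    x_min = cd$bbox[["x_min"]], y_min = cd$bbox[["y_min"]],
    x_max = cd$bbox[["x_max"]], y_max = cd$bbox[["y_max"]],
    area_px = cd$area_px, area_um2 = cd$area_px / resolution^2,
    centroid_row = cd$centroid[["row"]], centroid_col = cd$centroid[["col"]],
    mean_r = cd$mean_rgb[1], mean_g = cd$mean_rgb[2], mean_b = cd$mean_rgb[3])))
}
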