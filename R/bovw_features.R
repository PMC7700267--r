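# Bag-of-visual-words descriptors.
#
# A candidate's grown bounding box is described as an L1-normalized
# histogram of visual words. Words are k-means centroids in a base feature
# space: raw RGB triples (colour mode) or the 2*No-dimensional complex
# Gabor filter-bank responses (texture mode). Colour histograms deliberately
# include the background pixels of the grown box, which encodes
# foreground/background proportion as an implicit shape cue.

#' Gabor envelope spread for a given frequency bandwidth
#'
#' The spatial spread of the isotropic Gaussian envelope that yields a
#' half-magnitude frequency bandwidth of `B` octaves at central frequency
#' `fc`:
#' \deqn{\sigma = \frac{1}{\pi f_c}\sqrt{\frac{\ln 2}{2}}
#'       \, \frac{2^B + 1}{2^B - 1}.}
#'
#' @param fc Central frequency in cycles per pixel (> 0).
#' @param B Bandwidth in octaves (> 0).
#' @return Envelope spread in pixels.
#' @examples
#' gabor_sigma(0.25, 1.5)  # about 1.57 px
#' @export
gabor_sigma <- function(fc, B) {
  stopifnot(fc > 0, B > 0)
  (1 / (pi * fc)) * sqrt(log(2) / 2) * (2^B + 1) / (2^B - 1)
}

#' Build a complex Gabor filter bank
#'
#' `No` filters at one scale, evenly spaced orientations
#' `theta = 0, pi/No, ..., pi(No-1)/No`. The filter at orientation theta is
#' \deqn{g(x, y; \theta) = \frac{f_c^2}{2\pi\sigma^2}
#'   \exp\!\Big(-\frac{x'^2 + y'^2}{2\sigma^2}\Big)
#'   \exp(-j 2 \pi f_c x'),}
#' with rotated coordinates `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)` and sigma from [gabor_sigma()].
#' Kernels are sampled on an odd grid covering three spreads.
#'
#' @param fc Central frequency in cycles per pixel.
#' @param B Bandwidth in octaves.
#' @param No Number of orientations (the reference grids use 4 or 8).
#' @return A `gabor_bank`: fc, B, No, sigma, thetas and `No` complex kernels.
#' @export
build_gabor_bank <- function(fc, B, No) {
  stopifnot(No >= 1)
  sigma <- gabor_sigma(fc, B)
  r <- ceiling(3 * sigma)
  if (r < 1L)
    stop("Gabor envelope too small for a 3x3 kernel (sigma = ",
         signif(sigma, 4), " px)", call. = FALSE)
  off <- -r:r
  x <- matrix(off, 2 * r + 1, 2 * r + 1, byrow = TRUE)   # column offset
  y <- matrix(off, 2 * r + 1, 2 * r + 1)                 # row offset
  thetas <- pi * (seq_len(No) - 1) / No
  kernels <- lapply(thetas, function(th) {
    xp <- x * cos(th) + y * sin(th)
    yp <- -x * sin(th) + y * cos(th)
    amp <- fc^2 / (2 * pi * sigma^2)
    amp * exp(-(xp^2 + yp^2) / (2 * sigma^2)) *
      exp(-2i * pi * fc * xp)
  })
  structure(list(fc = fc, B = B, No = as.integer(No), sigma = sigma,
                 thetas = thetas, kernels = kernels), class = "gabor_bank")
}

# 2-D convolution of a real matrix with a list of complex kernels, reflect
# border handling, via one shared padded FFT of the input.
conv2_reflect <- function(mat, kernels, r) {
  H <- nrow(mat); W <- ncol(mat)
  ri <- c(pmin(r:1, H), 1:H, pmax(H - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, W), 1:W, pmax(W - seq_len(r) + 1L, 1L))
  ph <- stats::nextn(H + 2L * r, c(2, 3, 5))
  pw <- stats::nextn(W + 2L * r, c(2, 3, 5))
  xp <- matrix(0, ph, pw)
  xp[seq_len(H + 2L * r), seq_len(W + 2L * r)] <- mat[ri, ci]
  Fx <- stats::fft(xp)
  lapply(kernels, function(k) {
    kp <- matrix(0+0i, ph, pw)
    idx_r <- ((-r:r) %% ph) + 1L
    idx_c <- ((-r:r) %% pw) + 1L
    kp[idx_r, idx_c] <- k
    res <- stats::fft(Fx * stats::fft(kp), inverse = TRUE) / (ph * pw)
    res[(r + 1L):(r + H), (r + 1L):(r + W)]
  })
}

#' Grayscale luma of a microscopy image
#'
#' Fixed weights 0.299 / 0.587 / 0.114 on R / G / B.
#'
#' @param image A [microscopy_image()].
#' @return `H x W` numeric matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  0.299 * image$pixels[, , 1] + 0.587 * image$pixels[, , 2] +
    0.114 * image$pixels[, , 3]
}

#' Gabor filter-bank responses over a whole image
#'
#' The image is converted to grayscale and convolved with every complex
#' kernel of the bank. Responses are computed over the whole image before
#' any cropping into bounding boxes, which avoids aliasing from crop
#' boundaries; borders are handled by reflection. Channels are ordered
#' `(real_1, imag_1, real_2, imag_2, ...)`, one real/imaginary pair per
#' orientation, giving `2 * No` responses per pixel.
#'
#' @param image A [microscopy_image()].
#' @param bank A [build_gabor_bank()] bank.
#' @return `H x W x 2No` numeric array.
#' @export
texture_responses <- function(image, bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  gray <- to_grayscale(image)
  r <- (nrow(bank$kernels[[1]]) - 1L) / 2L
  res <- conv2_reflect(gray, bank$kernels, r)
  out <- array(0, dim = c(nrow(gray), ncol(gray), 2L * bank$No))
  for (i in seq_len(bank$No)) {
    out[, , 2L * i - 1L] <- Re(res[[i]])
    out[, , 2L * i] <- Im(res[[i]])
  }
  out
}

#' Build a visual-word dictionary by k-means
#'
#' Clusters base feature rows (RGB triples or Gabor response vectors) into
#' `k` visual words with MacQueen k-means under a fixed seed (5 random
#' starts), so the dictionary is deterministic given `(rows, k, seed)`.
#' Features are clustered unscaled; the scaling applied is recorded for
#' reproducibility.
#'
#' @param feature_rows `n x d` numeric matrix, `n >= k`.
#' @param k Number of visual words (>= 2).
#' @param seed Integer seed.
#' @param mode `"colour"` or `"texture"` (metadata).
#' @return A `bovw_dictionary` with a `k x d` centroid matrix.
#' @export
build_dictionary <- function(feature_rows, k, seed = 1L, mode = "colour") {
  feature_rows <- as.matrix(feature_rows)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (nrow(feature_rows) < k)
    stop("fewer feature rows (", nrow(feature_rows), ") than words requested (",
         k, "); reduce k", call. = FALSE)
  n_distinct <- nrow(unique(feature_rows))
  if (n_distinct < k)
    stop("only ", n_distinct, " distinct feature rows for k = ", k,
         "; reduce k", call. = FALSE)
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(feature_rows, centers = k, nstart = 5L, iter.max = 100L,
                  algorithm = "MacQueen")))
  structure(list(mode = mode, k = as.integer(k), d = ncol(feature_rows),
                 centroids = unname(km$centers), feature_scaling = "none",
                 seed = as.integer(seed)),
            class = "bovw_dictionary")
}

#' Visual-word histogram of a feature-row set
#'
#' Assigns every row to its nearest centroid (Euclidean; ties break to the
#' lowest centroid index) and returns the L1-normalized count histogram.
#'
#' @param region_rows `m x d` matrix, `m >= 1`, `d` matching the dictionary.
#' @param dict A [build_dictionary()] dictionary.
#' @return Numeric vector of length `k` summing to 1.
#' @export
bovw_histogram <- function(region_rows, dict) {
  region_rows <- matrix(as.numeric(region_rows), ncol = dict$d)
  if (nrow(region_rows) < 1L) stop("empty region", call. = FALSE)
  if (ncol(region_rows) != dict$d)
    stop("feature dimension ", ncol(region_rows),
         " does not match dictionary (", dict$d, ")", call. = FALSE)
  cent <- dict$centroids
  d2 <- outer(rowSums(region_rows^2), rowSums(cent^2), `+`) -
    2 * region_rows %*% t(cent)
  assign <- max.col(-d2, ties.method = "first")
  tabulate(assign, nbins = dict$k) / nrow(region_rows)
}

# Base feature rows of a grown candidate bbox.
region_feature_rows <- function(image, cand, mode, config, responses = NULL) {
  b <- grow_bbox(cand$bbox, config$bbox_growth_frac, dim(image$pixels)[1:2])
  rows <- (b[["y_min"]] + 1L):b[["y_max"]]
  cols <- (b[["x_min"]] + 1L):b[["x_max"]]
  if (mode == "colour") {
    px <- image$pixels[rows, cols, , drop = FALSE]
    matrix(as.numeric(px), ncol = 3L)
  } else {
    if (is.null(responses))
      stop("texture rows need precomputed whole-image responses", call. = FALSE)
    crop <- responses[rows, cols, , drop = FALSE]
    matrix(as.numeric(crop), ncol = dim(responses)[3])
  }
}

#' Describe a candidate as a BoVW histogram
#'
#' The candidate's bounding box is grown by `bbox_growth_frac` of its own
#' width/height on each side (clamped to the image), and all pixels of the
#' grown box contribute a base feature row. `mode = "both"` concatenates the
#' colour and texture histograms (each L1-normalized).
#'
#' @param image A [microscopy_image()].
#' @param cand A candidate.
#' @param mode `"colour"`, `"texture"` or `"both"`.
#' @param dicts Named list with elements `colour` and/or `texture`
#'   ([build_dictionary()] objects) as required by `mode`.
#' @param config A [pipeline_config()].
#' @param bank A [build_gabor_bank()] bank (texture modes).
#' @param responses Optional precomputed [texture_responses()] array;
#'   computed on demand from `bank` when missing.
#' @return Numeric descriptor vector.
#' @export
extract_descriptor <- function(image, cand, mode, dicts,
                               config = pipeline_config(), bank = NULL,
                               responses = NULL) {
  mode <- match.arg(mode, c("colour", "texture", "both"))
  shp <- dim(image$pixels)[1:2]
  b <- cand$bbox
  if (b[["x_min"]] < 0 || b[["y_min"]] < 0 ||
      b[["x_max"]] > shp[2] || b[["y_max"]] > shp[1])
    stop("candidate bbox lies outside the image", call. = FALSE)
  parts <- list()
  if (mode %in% c("colour", "both")) {
    if (is.null(dicts$colour)) stop("no colour dictionary supplied", call. = FALSE)
    parts$colour <- bovw_histogram(
      region_feature_rows(image, cand, "colour", config), dicts$colour)
  }
  if (mode %in% c("texture", "both")) {
    if (is.null(dicts$texture)) stop("no texture dictionary supplied", call. = FALSE)
    if (is.null(responses)) {
      if (is.null(bank)) stop("texture mode needs a Gabor bank", call. = FALSE)
      responses <- texture_responses(image, bank)
    }
    parts$texture <- bovw_histogram(
      region_feature_rows(image, cand, "texture", config, responses),
      dicts$texture)
  }
  unlist(parts, use.names = FALSE)
}

#' @rdname extract_descriptor
#' @param cands List of candidates; whole-image texture responses are
#'   computed once and shared.
#' @return `extract_descriptors()`: matrix with one row per candidate.
#' @export
extract_descriptors <- function(image, cands, mode, dicts,
                                config = pipeline_config(), bank = NULL) {
  mode <- match.arg(mode, c("colour", "texture", "both"))
  responses <- NULL
  if (mode %in% c("texture", "both")) {
    if (is.null(bank)) stop("texture mode needs a Gabor bank", call. = FALSE)
    responses <- texture_responses(image, bank)
  }
  do.call(rbind, lapply(cands, function(cd)
    extract_descriptor(image, cd, mode, dicts, config, bank, responses)))
}

#' Write or read a dictionary as JSON
#'
#' @param dict A `bovw_dictionary`.
#' @param path File path.
#' @export
write_dictionary <- function(dict, path) {
  jsonlite::write_json(unclass(dict), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$centroids <- matrix(unlist(x$centroids), nrow = x$k, byrow = FALSE)
  structure(x[c("mode", "k", "d", "centroids", "feature_scaling", "seed")],
            class = "bovw_dictionary")
}
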