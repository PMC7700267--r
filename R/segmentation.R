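# Foreground-background separation.
#
# Bright-field water samples show uneven illumination and shadows, so a
# global threshold is unusable. Each RGB channel is thresholded against a
# Gaussian-weighted local average minus a fixed offset, and the three
# channel masks are OR-fused so a specimen visible in any single channel is
# preserved.

# Gaussian-weighted local average with reflect border handling.
# Separable: two 1-D circular FFT convolutions on a reflect-padded grid,
# sized up to a (2,3,5)-smooth length so the FFT stays fast for any image.
gaussian_local_mean <- function(mat, sigma_px) {
  r <- ceiling(3 * sigma_px)            # kernel truncated at +/- 3 sigma
  if (r < 1L) r <- 1L
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  out <- conv1_reflect_cols(mat, k, r)
  t(conv1_reflect_cols(t(out), k, r))
}

conv1_reflect_cols <- function(m, k, r) {
  H <- nrow(m)
  idx <- c(pmin(r:1, H), 1:H, pmax(H - seq_len(r) + 1L, 1L))  # reflect pad
  L <- H + 2L * r
  n <- stats::nextn(L, c(2, 3, 5))
  xp <- matrix(0, n, ncol(m))
  xp[seq_len(L), ] <- m[idx, , drop = FALSE]
  kv <- numeric(n)
  kv[1L] <- k[r + 1L]
  kv[1L + seq_len(r)] <- k[r + 1L + seq_len(r)]
  kv[n - seq_len(r) + 1L] <- k[r + 1L - seq_len(r)]
  res <- Re(stats::mvfft(stats::mvfft(xp) * stats::fft(kv), inverse = TRUE)) / n
  res[(r + 1L):(r + H), , drop = FALSE]
}

#' Adaptive Gaussian threshold of one image channel
#'
#' A pixel is foreground iff its value is below the Gaussian-weighted local
#' average of the channel minus the offset `C = offset_frac * 255` (for the
#' default dark-foreground polarity: bright-field specimens absorb light, so
#' they are darker than the surrounding water). The window spread is stated
#' in micrometres so it scales with magnification; borders are handled by
#' reflection and the kernel is truncated at three spreads.
#'
#' @param channel `H x W` numeric matrix with values in `[0, 255]`.
#' @param sigma_um Gaussian window spread in micrometres (> 0).
#' @param offset_frac Offset as a fraction of the 8-bit dynamic range,
#'   in (0, 1). The offset is kept fractional (e.g. 0.08 -> 20.4 levels).
#' @param resolution Pixels per micrometre.
#' @param dark_foreground If `TRUE` (default), foreground is darker than the
#'   local average; if `FALSE`, brighter.
#' @return Logical `H x W` matrix, `TRUE` = foreground.
#' @export
adaptive_gaussian_threshold <- function(channel, sigma_um, offset_frac,
                                        resolution, dark_foreground = TRUE) {
  stopifnot(is.matrix(channel), sigma_um > 0,
            offset_frac > 0, offset_frac < 1)
  sigma_px <- um_to_px(sigma_um, resolution)
  if (sigma_px < 0.5)
    stop("adaptive threshold window degenerates: sigma is ", sigma_px,
         " px (< 0.5 px) at this resolution", call. = FALSE)
  g <- gaussian_local_mean(channel, sigma_px)
  C <- offset_frac * 255
  if (dark_foreground) channel < g - C else channel > g + C
}

#' Fuse per-channel masks with a pixelwise OR
#'
#' Keeps the most information among the channels: a pixel flagged as
#' foreground in any channel stays foreground, so the result is a superset
#' of every input mask.
#'
#' @param masks List of logical matrices of identical shape.
#' @return Logical matrix.
#' @export
fuse_channel_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1L]])
  for (m in masks)
    if (!is.logical(m) || !identical(dim(m), d))
      stop("all masks must be logical matrices of identical shape", call. = FALSE)
  Reduce(`|`, masks)
}

#' Segment the foreground of a microscopy image
#'
#' Applies [adaptive_gaussian_threshold()] to each RGB channel independently
#' and OR-fuses the three channel masks.
#'
#' @param image A [microscopy_image()].
#' @param config A [pipeline_config()].
#' @return Logical `H x W` matrix, `TRUE` = foreground.
#' @export
segment_foreground <- function(image, config = pipeline_config()) {
  stopifnot(inherits(image, "microscopy_image"))
  masks <- lapply(1:3, function(ch)
    adaptive_gaussian_threshold(image$pixels[, , ch],
                                sigma_um = config$threshold_sigma_um,
                                offset_frac = config$threshold_offset_frac,
                                resolution = image$resolution,
                                dark_foreground = config$dark_foreground))
  fuse_channel_masks(masks)
}
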