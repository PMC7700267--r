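#' Convert a physical length to pixels
#'
#' All thresholds in the pipeline are stated in micrometres, as is customary
#' for light microscopy; images carry a spatial resolution in pixels per
#' micrometre (about 1.5 px/um for a 12 Mpx camera at 10x magnification).
#' The conversion is kept exact: non-integer pixel values are not rounded.
#'
#' @param length_um Length in micrometres (non-negative).
#' @param resolution Spatial resolution in pixels per micrometre (> 0).
#' @return Length in pixels (real, unrounded).
#' @examples
#' um_to_px(75, 1.5)   # 112.5
#' um2_to_px2(5, 1.5)  # 11.25
#' @export
um_to_px <- function(length_um, resolution) {
  check_resolution(resolution)
  stopifnot(all(length_um >= 0))
  length_um * resolution
}

#' @rdname um_to_px
#' @param area_um2 Area in square micrometres (non-negative).
#' @export
um2_to_px2 <- function(area_um2, resolution) {
  check_resolution(resolution)
  stopifnot(all(area_um2 >= 0))
  area_um2 * resolution^2
}

check_resolution <- function(resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0) {
    stop("`resolution` must be a single positive number (pixels per um)",
         call. = FALSE)
  }
  invisible(resolution)
}

#' Construct a microscopy image object
#'
#' Bundles an 8-bit RGB pixel grid with its physical resolution and an
#' identifier. Pixels are stored as an `H x W x 3` integer array in RGB
#' order, values in `[0, 255]`, rows indexing the vertical axis.
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @param resolution Pixels per micrometre (> 0).
#' @param image_id Character identifier.
#' @return A `microscopy_image` object.
#' @export
microscopy_image <- function(pixels, resolution, image_id = "image") {
  check_resolution(resolution)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = dim(pixels)),
         resolution = as.numeric(resolution),
         image_id = as.character(image_id)),
    class = "microscopy_image")
}

#' @export
print.microscopy_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<microscopy_image> %s: %d x %d px (%.1f x %.1f um) at %.3g px/um\n",
              x$image_id, d[1], d[2],
              d[1] / x$resolution, d[2] / x$resolution, x$resolution))
  invisible(x)
}

#' Read an image file as a microscopy image
#'
#' Reads an 8-bit RGB PNG or TIFF. Grayscale images are either promoted to
#' three identical channels (`promote_gray = TRUE`) or rejected; images with
#' an alpha channel are accepted and the alpha plane dropped. 16-bit input
#' is rescaled linearly to 8-bit when promotion is enabled.
#'
#' @param path Path to a PNG or TIFF file.
#' @param resolution Pixels per micrometre of the acquisition.
#' @param image_id Identifier; defaults to the file name without extension.
#' @param promote_gray Promote 1-channel input to RGB and rescale non-8-bit
#'   input? If `FALSE`, such files are an error.
#' @return A [microscopy_image()].
#' @export
load_image <- function(path, resolution, image_id = NULL, promote_gray = TRUE) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expect PNG or TIFF)",
         call. = FALSE))
  # readers return values in [0,1] regardless of source bit depth
  if (length(dim(arr)) == 2L) {
    if (!promote_gray)
      stop("grayscale image and `promote_gray` is FALSE: ", path, call. = FALSE)
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (dim(arr)[3] == 4L) {
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3] == 2L) {  # gray + alpha
    if (!promote_gray)
      stop("grayscale image and `promote_gray` is FALSE: ", path, call. = FALSE)
    arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  } else if (dim(arr)[3] != 3L) {
    stop("unsupported channel count: ", dim(arr)[3], call. = FALSE)
  }
  microscopy_image(round(arr * 255), resolution,
                   image_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a microscopy image or binary mask to PNG
#'
#' @param x A [microscopy_image()] or a logical matrix (mask).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "microscopy_image")) {
    png::writePNG(x$pixels / 255, path)
  } else if (is.logical(x) && is.matrix(x)) {
    png::writePNG(x * 1.0, path)
  } else stop("`x` must be a microscopy_image or a logical mask", call. = FALSE)
  invisible(path)
}

# ---- bounding boxes ---------------------------------------------------------

#' Bounding boxes
#'
#' Boxes use 0-based pixel coordinates and are half-open:
#' `[x_min, x_max) x [y_min, y_max)`, with `x` indexing columns and `y` rows,
#' so `area = (x_max - x_min) * (y_max - y_min)`.
#'
#' @param x_min,y_min,x_max,y_max Integer pixel coordinates.
#' @return Named numeric vector of class `bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (x_min >= x_max || y_min >= y_max)
    stop("invalid bbox: require x_min < x_max and y_min < y_max", call. = FALSE)
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bbox")
}

bbox_area <- function(b) (b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]])

bbox_intersection_area <- function(a, b) {
  w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (w <= 0 || h <= 0) 0 else w * h
}

bbox_union <- function(a, b) {
  bbox(min(a[["x_min"]], b[["x_min"]]), min(a[["y_min"]], b[["y_min"]]),
       max(a[["x_max"]], b[["x_max"]]), max(a[["y_max"]], b[["y_max"]]))
}

#' Grow a bounding box by a fraction of its size, clamped to the image
#'
#' Each side moves outward by `round(frac * width)` (respectively height)
#' pixels, then the box is clamped to the image bounds. Classification uses
#' grown boxes so descriptors see some background context around a specimen.
#'
#' @param b A [bbox()].
#' @param frac Growth fraction per side (default 0.10).
#' @param image_shape `c(H, W)` in pixels.
#' @return Grown, clamped [bbox()].
#' @export
grow_bbox <- function(b, frac, image_shape) {
  gx <- round(frac * (b[["x_max"]] - b[["x_min"]]))
  gy <- round(frac * (b[["y_max"]] - b[["y_min"]]))
  bbox(max(0, b[["x_min"]] - gx), max(0, b[["y_min"]] - gy),
       min(image_shape[2], b[["x_max"]] + gx), min(image_shape[1], b[["y_max"]] + gy))
}

# ---- annotations ------------------------------------------------------------

GT_LABELS <- c("phytoplankton", "other")

#' Read and write ground-truth annotations
#'
#' Annotations are a CSV with header
#' `image_id,x_min,y_min,x_max,y_max,label`; coordinates follow the
#' package-wide 0-based half-open convention ([bbox()]) and `label` is one of
#' `"phytoplankton"` or `"other"`. Row order is preserved.
#'
#' @param path CSV file path.
#' @return `read_annotations()`: a data frame with one row per box.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    image_id = "character", x_min = "integer", y_min = "integer",
    x_max = "integer", y_max = "integer", label = "character"))
  required <- c("image_id", "x_min", "y_min", "x_max", "y_max", "label")
  if (!identical(names(df)[seq_along(required)], required))
    stop("annotation header must be ", paste(required, collapse = ","),
         call. = FALSE)
  if (nrow(df) == 0L) return(df)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (anyNA(r[c("x_min", "y_min", "x_max", "y_max")]))
      stop(sprintf("malformed annotation row %d: non-integer coordinates", i),
           call. = FALSE)
    if (r$x_min >= r$x_max || r$y_min >= r$y_max)
      stop(sprintf("invalid box on annotation row %d: require x_min < x_max and y_min < y_max", i),
           call. = FALSE)
    if (!r$label %in% GT_LABELS)
      stop(sprintf("invalid label %s on annotation row %d (expected one of: %s)",
                   dQuote(r$label), i, paste(GT_LABELS, collapse = ", ")),
           call. = FALSE)
  }
  df
}

#' @rdname read_annotations
#' @param annotations Data frame in the annotation layout.
#' @export
write_annotations <- function(annotations, path) {
  required <- c("image_id", "x_min", "y_min", "x_max", "y_max", "label")
  stopifnot(all(required %in% names(annotations)))
  utils::write.csv(annotations[, required, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Central container for every tunable of the pipeline, with physical
#' parameters in micrometres so they are independent of magnification:
#'
#' * `threshold_sigma_um` — spread of the adaptive threshold's Gaussian
#'   window (default 75 um; chosen larger than the target cells).
#' * `threshold_offset_frac` — offset C of the adaptive threshold as a
#'   fraction of the 8-bit dynamic range (default 0.08, i.e. C = 20.4).
#' * `min_area_um2` — candidates below this filled area are discarded
#'   (default 5 um^2).
#' * `merge_distance_um` — Delaunay edges longer than this are pruned
#'   (default 105 um).
#' * `merge_colour_frac` — per-channel colour difference above this fraction
#'   of the dynamic range prunes an edge (default 0.15, i.e. 38.25 levels).
#' * `bbox_growth_frac` — bounding-box growth per side before description
#'   (default 0.10).
#' * `resolution_px_per_um` — image resolution (default 1.5 px/um).
#' * `rng_seed` — master seed; all pipeline randomness derives from it.
#' * `dark_foreground` — if `TRUE` (default) foreground is darker than the
#'   local average, as for absorbing specimens in bright-field illumination.
#' * `colour_rule` — `"per_channel"` (default) prunes on any single channel
#'   exceeding the threshold; `"euclidean"` compares RGB distance against
#'   `merge_colour_frac * 255 * sqrt(3)`.
#'
#' @param ... Named overrides of the defaults above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    threshold_sigma_um = 75,
    threshold_offset_frac = 0.08,
    min_area_um2 = 5,
    merge_distance_um = 105,
    merge_colour_frac = 0.15,
    bbox_growth_frac = 0.10,
    resolution_px_per_um = 1.5,
    rng_seed = 1L,
    dark_foreground = TRUE,
    colour_rule = "per_channel")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  for (f in c("threshold_sigma_um", "min_area_um2", "merge_distance_um",
              "resolution_px_per_um"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("`", f, "` must be strictly positive", call. = FALSE)
  for (f in c("threshold_offset_frac", "merge_colour_frac", "bbox_growth_frac"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("`", f, "` must lie in (0, 1)", call. = FALSE)
  cfg$colour_rule <- match.arg(cfg$colour_rule, c("per_channel", "euclidean"))
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON file whose top-level keys mirror the
#'   configuration fields.
#' @export
read_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides  # explicit arguments beat file values
  do.call(pipeline_config, vals)
}
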