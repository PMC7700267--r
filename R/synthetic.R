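# Seeded synthetic bright-field scenes with exact ground truth.
#
# The generator emulates the imaging conditions the pipeline is designed
# for: a bright background with a smooth illumination gradient and sensor
# noise; dark compact specimens (ellipses) with a sinusoidal,
# Gabor-detectable texture; sparse colonies of small disconnected cells
# sharing a base colour; debris with a colour offset beyond the merge
# threshold and uncorrelated speckle texture; optionally an object touching
# the image border. Object placement respects the configured merge
# thresholds by construction, so colony structure is recoverable: cells of
# one colony stay within the merge distance and colour jitter, while
# distinct objects either differ in colour beyond the threshold or sit
# beyond the merge distance.

#' Synthetic scene specification
#'
#' Defaults give a 512 x 384 px field at 1.5 px/um (about 341 x 256 um)
#' with 2-4 solid specimens, 1-2 sparse colonies of 4-7 cells and 1-2
#' debris objects. All sizes are in micrometres. `merge_distance_um` /
#' `merge_colour_frac` mirror the pipeline defaults the scene is built to
#' respect.
#'
#' @param ... Named overrides of the defaults (see source for fields).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(...) {
  spec <- list(
    width = 512L, height = 384L, resolution = 1.5,
    background_level = 220, illumination_amplitude = 25, noise_sd = 3,
    n_blobs = c(2L, 4L), n_colonies = c(1L, 2L), n_debris = c(1L, 2L),
    blob_radius_um = c(5, 12),
    colony_cells = c(4L, 7L), colony_cell_radius_um = c(3.5, 6),
    colony_spacing_um = c(25, 55), colony_colour_jitter = 8,
    specimen_palettes = list(c(60, 105, 55), c(125, 85, 45), c(55, 95, 120)),
    debris_palettes = list(c(150, 150, 185), c(170, 165, 120)),
    texture_freq = 0.25, texture_amplitude = 15, speckle_amplitude = 25,
    edge_touch_prob = 0.25,
    merge_distance_um = 105, merge_colour_frac = 0.15,
    similar_colour_sep_um = 130,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown))
    stop("unknown scene_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec[names(dots)] <- dots
  stopifnot(spec$width >= 64L, spec$height >= 64L, spec$resolution > 0)
  # intra-colony geometry must respect the merge thresholds by construction
  stopifnot(max(spec$colony_spacing_um) <= spec$merge_distance_um,
            2 * spec$colony_colour_jitter < spec$merge_colour_frac * 255)
  structure(spec, class = "scene_spec")
}

rand_int <- function(range) {
  if (range[1] >= range[length(range)]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[length(range)]), 1L)
}

# per-channel palette gap large enough that rendered mean colours stay
# apart after texture and illumination shifts
palettes_similar <- function(a, b, threshold) max(abs(a - b)) < threshold + 17

ellipse_pixels <- function(H, W, cy, cx, a, b, phi) {
  r0 <- max(1L, floor(cy - a - b)); r1 <- min(H, ceiling(cy + a + b))
  c0 <- max(1L, floor(cx - a - b)); c1 <- min(W, ceiling(cx + a + b))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  y <- matrix(rr - cy, length(rr), length(cc))
  x <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  cbind(row = rr[w[, 1]], col = cc[w[, 2]])
}

#' Generate a synthetic scene
#'
#' Deterministic given `spec$seed`: renders the objects, applies the
#' illumination gradient and additive Gaussian noise (clipped to
#' `[0, 255]`), and returns the image together with exact truth boxes and
#' the colony membership map.
#'
#' @param spec A [scene_spec()].
#' @param image_id Identifier for the generated image.
#' @return A `synthetic_scene`: `image` ([microscopy_image()]), `truth`
#'   (annotation data frame with extra `kind` and `edge_touching` columns),
#'   and `colony_map` (specimen id -> member blob ids).
#' @export
generate_scene <- function(spec = scene_spec(), image_id = "synthetic") {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec, image_id))
}

generate_scene_impl <- function(spec, image_id) {
  H <- spec$height; W <- spec$width; res <- spec$resolution
  px_r <- function(um) um * res
  img <- array(spec$background_level, dim = c(H, W, 3))

  # illumination gradient: a tilted plane in a random direction
  ang <- stats::runif(1, 0, 2 * pi)
  gr <- spec$illumination_amplitude *
    (outer((seq_len(H) / H - 0.5) * sin(ang), rep(1, W)) +
     outer(rep(1, H), (seq_len(W) / W - 0.5) * cos(ang)))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + gr

  objects <- list()   # placed objects: centre (row,col px), radius px, palette
  truth <- list()
  colony_map <- list()
  specimen_id <- 0L
  blob_id <- 0L

  min_sep_similar <- px_r(spec$similar_colour_sep_um)
  colour_threshold <- spec$merge_colour_frac * 255

  placement_ok <- function(cy, cx, rad, palette) {
    for (ob in objects) {
      d <- sqrt((cy - ob$cy)^2 + (cx - ob$cx)^2)
      if (d < rad + ob$rad + px_r(8)) return(FALSE)        # no near-touching
      if (palettes_similar(palette, ob$palette, colour_threshold) &&
          d < min_sep_similar) return(FALSE)
    }
    TRUE
  }

  sample_centre <- function(rad, palette, edge = FALSE) {
    for (try in seq_len(300L)) {
      if (edge) {
        side <- sample(4L, 1L)
        off <- stats::runif(1, 0.2 * rad, 0.8 * rad)
        cy <- switch(side, 1 - off, H + off, stats::runif(1, rad + 6, H - rad - 6),
                     stats::runif(1, rad + 6, H - rad - 6))
        cx <- switch(side, stats::runif(1, rad + 6, W - rad - 6),
                     stats::runif(1, rad + 6, W - rad - 6), 1 - off, W + off)
      } else {
        if (2 * (rad + 6) >= min(H, W)) next
        cy <- stats::runif(1, rad + 6, H - rad - 6)
        cx <- stats::runif(1, rad + 6, W - rad - 6)
      }
      if (placement_ok(cy, cx, rad, palette)) return(c(cy, cx))
    }
    NULL
  }

  paint <- function(pix, palette, texture) {
    # texture: "sinusoid" for specimens, "speckle" for debris
    if (is.null(pix)) return(invisible())
    if (texture == "sinusoid") {
      phi <- stats::runif(1, 0, pi)
      mod <- spec$texture_amplitude *
        sin(2 * pi * spec$texture_freq *
            (pix[, "col"] * cos(phi) + pix[, "row"] * sin(phi)))
    } else {
      mod <- stats::runif(nrow(pix), -spec$speckle_amplitude,
                          spec$speckle_amplitude)
    }
    for (ch in 1:3)
      img[cbind(pix[, "row"], pix[, "col"], ch)] <<- palette[ch] + mod
    invisible()
  }

  pix_bbox <- function(pix)
    c(x_min = min(pix[, "col"]) - 1L, y_min = min(pix[, "row"]) - 1L,
      x_max = max(pix[, "col"]), y_max = max(pix[, "row"]))

  add_truth <- function(pix, label, kind, edge = FALSE) {
    b <- pix_bbox(pix)
    truth[[length(truth) + 1L]] <<- data.frame(
      image_id = image_id, x_min = b[["x_min"]], y_min = b[["y_min"]],
      x_max = b[["x_max"]], y_max = b[["y_max"]], label = label,
      kind = kind, edge_touching = edge)
    length(truth)
  }

  place_blob <- function(kind, edge = FALSE) {
    specimen <- kind != "debris"
    palettes <- if (specimen) spec$specimen_palettes else spec$debris_palettes
    r_um <- stats::runif(1, spec$blob_radius_um[1], spec$blob_radius_um[2])
    rad <- px_r(r_um)
    # try palettes in random order: a colour crowded out by a similar
    # neighbour falls back to another palette before giving up
    ctr <- NULL
    for (palette in sample(palettes)) {
      ctr <- sample_centre(rad, palette, edge)
      if (!is.null(ctr)) break
    }
    if (is.null(ctr)) {
      if (edge) return(invisible(NULL))   # the border object is optional
      stop("infeasible packing: could not place a ", kind,
           " after bounded rejection sampling", call. = FALSE)
    }
    ecc <- stats::runif(1, 0.6, 1)
    pix <- ellipse_pixels(H, W, ctr[1], ctr[2], rad, rad * ecc,
                          stats::runif(1, 0, pi))
    if (is.null(pix)) return(invisible(NULL))  # fell entirely off-frame
    paint(pix, palette, if (specimen) "sinusoid" else "speckle")
    objects[[length(objects) + 1L]] <<-
      list(cy = ctr[1], cx = ctr[2], rad = rad, palette = palette)
    blob_id <<- blob_id + 1L
    add_truth(pix, if (specimen) "phytoplankton" else "other",
              kind, edge = edge)
    blob_id
  }

  place_colony <- function(palette) {
    n_cells <- rand_int(spec$colony_cells)
    extent <- px_r(max(spec$colony_spacing_um))
    ctr <- sample_centre(extent, palette)
    if (is.null(ctr))
      stop("infeasible packing: could not place a colony after bounded ",
           "rejection sampling", call. = FALSE)
    cells <- list()
    all_pix <- NULL
    members <- integer(0)
    for (k in seq_len(n_cells)) {
      r_um <- stats::runif(1, spec$colony_cell_radius_um[1],
                           spec$colony_cell_radius_um[2])
      rad <- px_r(r_um)
      placed <- FALSE
      for (try in seq_len(300L)) {
        if (k == 1L) { cy <- ctr[1]; cx <- ctr[2] }
        else {
          anchor <- cells[[sample(length(cells), 1L)]]
          d_um <- stats::runif(1, spec$colony_spacing_um[1],
                               spec$colony_spacing_um[2])
          a <- stats::runif(1, 0, 2 * pi)
          cy <- anchor$cy + px_r(d_um) * sin(a)
          cx <- anchor$cx + px_r(d_um) * cos(a)
        }
        if (cy < rad + 6 || cy > H - rad - 6 ||
            cx < rad + 6 || cx > W - rad - 6) next
        # visually disconnected from sibling cells, but within merge range
        ok <- TRUE
        for (cell in cells) {
          d <- sqrt((cy - cell$cy)^2 + (cx - cell$cx)^2)
          if (d < rad + cell$rad + 4) { ok <- FALSE; break }
          }
        if (ok && placement_ok(cy, cx, rad, palette)) { placed <- TRUE; break }
      }
      if (!placed) {
        if (k <= 2L)
          stop("infeasible packing: could not place colony cells", call. = FALSE)
        break   # accept a smaller colony
      }
      jit <- stats::runif(3, -spec$colony_colour_jitter,
                          spec$colony_colour_jitter)
      pix <- ellipse_pixels(H, W, cy, cx, rad, rad * stats::runif(1, 0.75, 1),
                            stats::runif(1, 0, pi))
      paint(pix, palette + jit, "sinusoid")
      cells[[length(cells) + 1L]] <- list(cy = cy, cx = cx, rad = rad)
      blob_id <<- blob_id + 1L
      members <- c(members, blob_id)
      all_pix <- rbind(all_pix, pix)
    }
    # register colony cells as one object footprint for later placements
    for (cell in cells)
      objects[[length(objects) + 1L]] <<-
        list(cy = cell$cy, cx = cell$cx, rad = cell$rad, palette = palette)
    tid <- add_truth(all_pix, "phytoplankton", "colony")
    colony_map[[as.character(tid)]] <<- members
    tid
  }

  # colonies first: they have the largest placement footprint; palettes are
  # drawn without replacement so two colonies never share a colour
  n_col <- rand_int(spec$n_colonies)
  col_pal <- sample(spec$specimen_palettes)
  for (i in seq_len(n_col))
    place_colony(col_pal[[((i - 1L) %% length(col_pal)) + 1L]])
  for (i in seq_len(rand_int(spec$n_blobs))) place_blob("blob")
  for (i in seq_len(rand_int(spec$n_debris))) place_blob("debris")
  if (stats::runif(1) < spec$edge_touch_prob) place_blob("blob", edge = TRUE)

  img <- img + array(stats::rnorm(H * W * 3, 0, spec$noise_sd), dim = dim(img))
  img <- pmin(pmax(round(img), 0), 255)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(image_id = character(), x_min = integer(), y_min = integer(),
               x_max = integer(), y_max = integer(), label = character(),
               kind = character(), edge_touching = logical())
  structure(list(
    image = microscopy_image(img, spec$resolution, image_id),
    truth = truth_df,
    colony_map = colony_map), class = "synthetic_scene")
}

#' Generate a seeded synthetic dataset with a train/test split
#'
#' Per-image seeds are derived from the master seed, so the dataset is
#' reproducible as a whole and no two images are identical.
#'
#' @param n_images Number of scenes (>= 2).
#' @param spec A [scene_spec()] template; its seed field is overridden per
#'   image.
#' @param seed Master seed.
#' @param split Fraction of images assigned to the training set.
#' @param out_dir Optional directory: scenes are written as PNGs plus an
#'   `annotations.csv` and `colony_map.json`.
#' @return List with `train` and `test` scene lists and the pooled
#'   `annotations` data frame.
#' @export
generate_dataset <- function(n_images, spec = scene_spec(), seed = 1L,
                             split = 0.5, out_dir = NULL) {
  stopifnot(n_images >= 2L, split > 0, split < 1)
  scenes <- lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, "scene", i)
    generate_scene(s, image_id = sprintf("synt%03d", i))
  })
  n_train <- max(1L, round(split * n_images))
  annotations <- do.call(rbind, lapply(scenes, function(sc)
    sc$truth[, c("image_id", "x_min", "y_min", "x_max", "y_max", "label")]))
  out <- list(train = scenes[seq_len(n_train)],
              test = scenes[setdiff(seq_len(n_images), seq_len(n_train))],
              annotations = annotations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sc in scenes)
      write_image(sc$image, file.path(out_dir, paste0(sc$image$image_id, ".png")))
    write_annotations(annotations, file.path(out_dir, "annotations.csv"))
    cmap <- lapply(scenes, function(sc) sc$colony_map)
    names(cmap) <- vapply(scenes, function(sc) sc$image$image_id, character(1))
    jsonlite::write_json(cmap, file.path(out_dir, "colony_map.json"))
  }
  out
}
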