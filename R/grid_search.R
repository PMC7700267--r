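# Two-stage cross-validated grid search.
#
# Stage 1 fixes the classifier at its default hyperparameters and searches
# the descriptor parameters (word counts, and for texture the Gabor
# frequency, bandwidth and orientation count), scoring each configuration
# by mean precision at the target recall over stratified held-out folds.
# Stage 2 re-searches the classifier hyperparameters with the stage-1
# descriptor fixed. Visual-word dictionaries are rebuilt inside each
# training fold only, so held-out candidates never influence the words they
# are scored against.

#' Prepare training material from annotated images
#'
#' Runs candidate detection and colony merging on every image and labels
#' the resulting candidates against the annotations. The result is the unit
#' of input for [grid_search()] and [run_train()]: the classification stage
#' trains on detected candidates, not on ground-truth boxes.
#'
#' @param images List of [microscopy_image()] objects.
#' @param annotations Annotation data frame covering the images.
#' @param config A [pipeline_config()].
#' @return A `training_material` list (images, candidates, labels, config).
#' @export
prepare_training_material <- function(images, annotations,
                                      config = pipeline_config()) {
  cands <- lapply(images, function(img) {
    merged <- merge_colonies(detect_candidates(img, config), config,
                             resolution = img$resolution,
                             image_id = img$image_id)
    merged
  })
  labels <- mapply(function(img, cd) {
    gts <- annotations[annotations$image_id == img$image_id, , drop = FALSE]
    if (length(cd)) label_candidates(cd, gts) else integer(0)
  }, images, cands, SIMPLIFY = FALSE)
  structure(list(images = images, cands = cands, labels = labels,
                 config = config), class = "training_material")
}

#' Descriptor parameter grid
#'
#' Expands the supplied parameter vectors into a list of descriptor
#' configurations in declared order (word counts vary fastest). The
#' reference search used word counts
#' `100, 50, 20, 10, 8, 5, 3, 2`, frequencies `0.5 ... 0.01105` in
#' half-octave steps, bandwidths `2, 1.5, 1, 0.5` and `4` or `8`
#' orientations; any subset may be searched.
#'
#' @param mode `"colour"`, `"texture"` or `"both"`.
#' @param kc,kt Word counts for the colour / texture dictionaries.
#' @param fc,B,No Gabor bank parameters (texture modes).
#' @return List of named configuration lists.
#' @export
descriptor_grid <- function(mode, kc = 10, kt = 10, fc = 0.25, B = 1.5,
                            No = 4) {
  mode <- match.arg(mode, c("colour", "texture", "both"))
  g <- switch(mode,
    colour = expand.grid(kc = kc),
    texture = expand.grid(kt = kt, fc = fc, B = B, No = No),
    both = expand.grid(kc = kc, kt = kt, fc = fc, B = B, No = No))
  lapply(seq_len(nrow(g)), function(i) c(mode = mode, as.list(g[i, , drop = FALSE])))
}

# Base feature rows per candidate for one descriptor configuration,
# computed once per image (texture responses whole-image-first).
material_feature_rows <- function(material, mode, dcfg, bank = NULL) {
  config <- material$config
  out <- list(colour = NULL, texture = NULL)
  if (mode %in% c("colour", "both")) {
    out$colour <- unlist(lapply(seq_along(material$images), function(i) {
      img <- material$images[[i]]
      lapply(material$cands[[i]], function(cd)
        region_feature_rows(img, cd, "colour", config))
    }), recursive = FALSE)
  }
  if (mode %in% c("texture", "both")) {
    out$texture <- unlist(lapply(seq_along(material$images), function(i) {
      img <- material$images[[i]]
      resp <- texture_responses(img, bank)
      lapply(material$cands[[i]], function(cd)
        region_feature_rows(img, cd, "texture", config, resp))
    }), recursive = FALSE)
  }
  out
}

# Histogram descriptors for a set of candidates given per-candidate base
# rows and fold-local dictionaries.
rows_to_descriptors <- function(rows, dicts, mode, idx) {
  part <- function(which_rows, dict)
    do.call(rbind, lapply(idx, function(i) bovw_histogram(which_rows[[i]], dict)))
  if (mode == "colour") part(rows$colour, dicts$colour)
  else if (mode == "texture") part(rows$texture, dicts$texture)
  else cbind(part(rows$colour, dicts$colour), part(rows$texture, dicts$texture))
}

cv_fitness <- function(rows, labels, fold_of, folds, mode, kind, hp, dcfg,
                       target_recall, seed) {
  fits <- c()
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); va <- which(fold_of == f)
    if (!any(labels[va] == 1)) {
      warning("fold ", f, " has no positive candidates; excluded from fitness")
      next
    }
    if (length(unique(labels[tr])) < 2L) {
      warning("fold ", f, " leaves a single-class training split; excluded")
      next
    }
    dicts <- list()
    ok <- tryCatch({
      if (mode %in% c("colour", "both"))
        dicts$colour <- build_dictionary(
          do.call(rbind, rows$colour[tr]), k = dcfg$kc,
          seed = derive_seed(seed, "dict_colour", f), mode = "colour")
      if (mode %in% c("texture", "both"))
        dicts$texture <- build_dictionary(
          do.call(rbind, rows$texture[tr]), k = dcfg$kt,
          seed = derive_seed(seed, "dict_texture", f), mode = "texture")
      TRUE
    }, error = function(e) {
      warning("descriptor configuration skipped in fold ", f, ": ",
              conditionMessage(e))
      FALSE
    })
    if (!ok) next
    xtr <- rows_to_descriptors(rows, dicts, mode, tr)
    xva <- rows_to_descriptors(rows, dicts, mode, va)
    model <- train_classifier(list(descriptors = xtr, labels = labels[tr]),
                              kind, hp, seed = derive_seed(seed, "clf", f))
    s <- predict_scores(model, xva)
    fits <- c(fits, precision_at_recall(s, labels[va], target_recall))
  }
  if (!length(fits)) NA_real_ else mean(fits)
}

#' Two-stage cross-validated grid search
#'
#' @param material A [prepare_training_material()] object.
#' @param mode Descriptor mode: `"colour"`, `"texture"` or `"both"`.
#' @param kind Classifier kind (see [train_classifier()]).
#' @param desc_grid List of descriptor configurations
#'   ([descriptor_grid()]).
#' @param clf_grid List of classifier hyperparameter settings searched in
#'   stage 2; defaults to the kind's default setting only.
#' @param folds Number of stratified cross-validation folds (default 5).
#' @param target_recall Fitness is precision at this recall (default 0.9).
#' @param seed Master seed; fold assignment depends only on
#'   `(seed, labels)`.
#' @return A `grid_search_result`: best configuration, its fitness, and the
#'   per-configuration cross-validation tables of both stages. Ties break
#'   to the earliest configuration in grid order.
#' @export
grid_search <- function(material, mode, kind, desc_grid,
                        clf_grid = list(default_hyperparams(kind)),
                        folds = 5L, target_recall = 0.9, seed = 1L) {
  mode <- match.arg(mode, c("colour", "texture", "both"))
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  stopifnot(length(desc_grid) >= 1L, length(clf_grid) >= 1L, folds >= 2L)
  labels <- unlist(material$labels)
  fold_of <- stratified_folds(labels, folds, seed)

  eval_desc <- function(dcfg, hp) {
    bank <- if (mode %in% c("texture", "both"))
      build_gabor_bank(dcfg$fc, dcfg$B, dcfg$No) else NULL
    rows <- material_feature_rows(material, mode, dcfg, bank)
    cv_fitness(rows, labels, fold_of, folds, mode, kind, hp, dcfg,
               target_recall, seed)
  }

  # stage 1: descriptor parameters at default hyperparameters
  fit1 <- vapply(desc_grid, eval_desc, numeric(1),
                 hp = default_hyperparams(kind))
  if (all(is.na(fit1)))
    stop("no descriptor configuration could be evaluated", call. = FALSE)
  best_d <- which(fit1 == max(fit1, na.rm = TRUE))[1L]

  # stage 2: classifier hyperparameters at the selected descriptor; the
  # default setting was already evaluated in stage 1, so reuse its fitness
  fit2 <- vapply(clf_grid, function(hp) {
    if (identical(hp, default_hyperparams(kind))) fit1[best_d]
    else eval_desc(desc_grid[[best_d]], hp)
  }, numeric(1))
  best_h <- which(fit2 == max(fit2, na.rm = TRUE))[1L]

  structure(list(
    mode = mode, kind = kind,
    best_descriptor = desc_grid[[best_d]],
    best_hyperparams = clf_grid[[best_h]],
    fitness = fit2[best_h],
    stage1 = data.frame(config = vapply(desc_grid, function(g)
      paste(names(g), unlist(g), sep = "=", collapse = " "), character(1)),
      fitness = fit1),
    stage2 = data.frame(config = vapply(clf_grid, function(g)
      paste(names(g), unlist(g), sep = "=", collapse = " "), character(1)),
      fitness = fit2),
    folds = folds, target_recall = target_recall, seed = seed),
    class = "grid_search_result")
}
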