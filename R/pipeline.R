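# End-to-end orchestration: segment -> detect -> merge -> featurize ->
# score -> threshold. All randomness funnels through the configuration's
# master seed; per-stage seeds are derived deterministically from it.

#' Train the full detection pipeline on annotated images
#'
#' Detects and merges candidates on every training image, labels them
#' against the annotations, runs the two-stage cross-validated grid search,
#' rebuilds the visual dictionaries on the whole training set with the
#' selected configuration, trains the final classifier on all training
#' candidates and places the operating threshold at the target recall on
#' the training scores.
#'
#' @param images List of [microscopy_image()] training images.
#' @param annotations Annotation data frame covering the images.
#' @param config A [pipeline_config()].
#' @param mode Descriptor mode: `"colour"`, `"texture"` or `"both"`.
#' @param kind Classifier kind (see [train_classifier()]).
#' @param desc_grid Descriptor grid ([descriptor_grid()]); defaults to a
#'   single moderate configuration per mode.
#' @param clf_grid Classifier hyperparameter grid; defaults to the kind's
#'   default setting.
#' @param folds,target_recall Cross-validation folds and fitness recall.
#' @return A `phyto_model` bundle (dictionaries, Gabor bank, classifier,
#'   operating threshold, grid-search result, configuration).
#' @export
run_train <- function(images, annotations, config = pipeline_config(),
                      mode = "colour", kind = "rf",
                      desc_grid = NULL, clf_grid = NULL,
                      folds = 5L, target_recall = 0.9) {
  mode <- match.arg(mode, c("colour", "texture", "both"))
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  desc_grid <- desc_grid %||% descriptor_grid(mode)
  clf_grid <- clf_grid %||% list(default_hyperparams(kind))
  material <- prepare_training_material(images, annotations, config)
  labels <- unlist(material$labels)
  if (!any(labels == 1))
    stop("no positive candidates after labelling; cannot train", call. = FALSE)
  gs <- grid_search(material, mode, kind, desc_grid, clf_grid,
                    folds = folds, target_recall = target_recall,
                    seed = config$rng_seed)
  best <- gs$best_descriptor
  bank <- if (mode %in% c("texture", "both"))
    build_gabor_bank(best$fc, best$B, best$No) else NULL
  rows <- material_feature_rows(material, mode, best, bank)
  dicts <- list()
  if (mode %in% c("colour", "both"))
    dicts$colour <- build_dictionary(do.call(rbind, rows$colour), k = best$kc,
                                     seed = derive_seed(config$rng_seed, "dict_colour"),
                                     mode = "colour")
  if (mode %in% c("texture", "both"))
    dicts$texture <- build_dictionary(do.call(rbind, rows$texture), k = best$kt,
                                      seed = derive_seed(config$rng_seed, "dict_texture"),
                                      mode = "texture")
  x <- rows_to_descriptors(rows, dicts, mode, seq_along(labels))
  clf <- train_classifier(list(descriptors = x, labels = labels), kind,
                          gs$best_hyperparams,
                          seed = derive_seed(config$rng_seed, "clf_final"))
  scores <- predict_scores(clf, x)
  th <- choose_operating_threshold(scores, labels, target_recall)
  structure(list(mode = mode, kind = kind, config = config,
                 dicts = dicts, bank = bank, classifier = clf,
                 operating_threshold = as.numeric(th),
                 train_precision = attr(th, "precision"),
                 grid = gs, version = "1"),
            class = "phyto_model")
}

#' @export
print.phyto_model <- function(x, ...) {
  cat(sprintf("<phyto_model> %s classifier, %s descriptors; threshold %.4g (train precision %.3f)\n",
              toupper(x$kind), x$mode, x$operating_threshold,
              x$train_precision))
  invisible(x)
}

#' Run the trained pipeline on images
#'
#' For each image: candidate detection, colony merging, descriptor
#' extraction with the model's dictionaries, classifier scoring, and the
#' model's operating threshold. The returned table has one row per merged
#' candidate with its score and accept/reject decision.
#'
#' @param images List of [microscopy_image()] objects.
#' @param model A [run_train()] model.
#' @param config Configuration; defaults to the model's.
#' @param keep_all Keep rejected candidates in the table (default TRUE;
#'   filter on `decision` for final detections).
#' @param verbose Emit per-stage log lines?
#' @return Data frame of detections.
#' @export
run_detect <- function(images, model, config = model$config,
                       keep_all = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "phyto_model"))
  out <- lapply(images, function(img) {
    cands <- detect_candidates(img, config, verbose = verbose)
    cands <- merge_colonies(cands, config, resolution = img$resolution,
                            verbose = verbose, image_id = img$image_id)
    if (!length(cands)) return(NULL)
    x <- extract_descriptors(img, cands, model$mode, model$dicts, config,
                             model$bank)
    s <- predict_scores(model$classifier, x)
    df <- candidates_to_df(cands, img$image_id, img$resolution)
    df$score <- s
    df$decision <- as.integer(s >= model$operating_threshold)
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(cbind(candidates_to_df(list()), score = numeric(0),
                 decision = integer(0)))
  do.call(rbind, out)
}

#' Save or load a trained model bundle
#'
#' @param model A `phyto_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "phyto_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "phyto_model"))
  model
}

#' Write a detections table to CSV with stable formatting
#'
#' Scores are written with 12 significant digits so repeated runs with the
#' same seed produce byte-identical files.
#'
#' @param detections Data frame from [run_detect()].
#' @param path Output CSV path.
#' @export
write_detections <- function(detections, path) {
  df <- detections
  for (cl in names(df))
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], digits = 12, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
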