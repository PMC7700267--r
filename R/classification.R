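# Phytoplankton-vs-other classification of candidate descriptors.
#
# Five classical classifiers are supported: random forest (RF), RBF support
# vector machine (SVM), k-nearest neighbours (kNN), boosted trees (BT,
# gradient-boosted decision trees) and Gaussian mixture models (GMM, one
# mixture per class scored by the class-conditional log-likelihood
# difference plus the log prior ratio). Every model exposes a real-valued
# score, higher = more phytoplankton-like, so the operating point can be
# placed at a target recall.

CLASSIFIER_KINDS <- c("rf", "svm", "knn", "bt", "gmm")

#' Label candidates against ground truth
#'
#' A candidate is positive (1) iff its bounding box overlaps at least half
#' of the area of some phytoplankton ground-truth box. Overlap is measured
#' against the ground-truth box's area, not intersection-over-union.
#'
#' @param cands List of candidates from one image.
#' @param gts Annotation data frame (see [read_annotations()]) for the same
#'   image.
#' @return Integer vector of 0/1 labels.
#' @export
label_candidates <- function(cands, gts) {
  phyto <- gts[gts$label == "phytoplankton", , drop = FALSE]
  vapply(cands, function(cd) {
    for (i in seq_len(nrow(phyto))) {
      g <- bbox(phyto$x_min[i], phyto$y_min[i], phyto$x_max[i], phyto$y_max[i])
      if (bbox_intersection_area(cd$bbox, g) >= 0.5 * bbox_area(g))
        return(1L)
    }
    0L
  }, integer(1))
}

default_hyperparams <- function(kind) {
  switch(kind,
         rf = list(ntree = 200L),
         svm = list(cost = 1, gamma = NULL),   # NULL gamma -> 1/d
         knn = list(k = 5L),
         bt = list(nrounds = 50L, max_depth = 3L, eta = 0.3),
         gmm = list(components = 1L))
}

# Diagonal-covariance Gaussian log-density, the fallback when a class is
# too small or too degenerate for an EM mixture fit.
diag_gauss_fit <- function(x) {
  list(mean = colMeans(x), var = apply(x, 2, stats::var) + 1e-6)
}
diag_gauss_logdens <- function(fit, x) {
  -0.5 * colSums((t(x) - fit$mean)^2 / fit$var) -
    0.5 * sum(log(2 * pi * fit$var))
}

fit_class_density <- function(x, components) {
  if (nrow(x) < max(3L, components + 1L))
    return(list(type = "diag", fit = diag_gauss_fit(x)))
  dens <- tryCatch(
    suppressWarnings(mclust::densityMclust(x, G = components, verbose = FALSE,
                                           plot = FALSE)),
    error = function(e) NULL)
  if (is.null(dens)) list(type = "diag", fit = diag_gauss_fit(x))
  else list(type = "mclust", fit = dens)
}

class_logdens <- function(model, x) {
  if (model$type == "diag") diag_gauss_logdens(model$fit, x)
  else {
    p <- stats::predict(model$fit, x, what = "dens", logarithm = TRUE)
    as.numeric(p)
  }
}

#' Train a phytoplankton-vs-other classifier
#'
#' @param data List with `descriptors` (`n x d` matrix) and `labels`
#'   (0/1 integer vector, 1 = phytoplankton); both classes must be present.
#' @param kind One of `"rf"`, `"svm"`, `"knn"`, `"bt"`, `"gmm"`.
#' @param hyperparams Named list overriding the kind's defaults
#'   (RF: `ntree`; SVM: `cost`, `gamma`; kNN: `k`; BT: `nrounds`,
#'   `max_depth`, `eta`; GMM: `components` per class).
#' @param seed Integer seed; training is deterministic given data and seed.
#' @return A `phyto_classifier`.
#' @export
train_classifier <- function(data, kind = CLASSIFIER_KINDS,
                             hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(data$descriptors)
  y <- as.integer(data$labels)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(kind), hyperparams)
  fit <- switch(kind,
    rf = with_seed(seed,
      randomForest::randomForest(x = x, y = factor(y, levels = c(0L, 1L)),
                                 ntree = hp$ntree)),
    svm = with_seed(seed,
      e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
                 kernel = "radial", cost = hp$cost,
                 gamma = hp$gamma %||% (1 / ncol(x)), scale = FALSE)),
    knn = list(train = x, cl = factor(y, levels = c(0L, 1L)), k = hp$k),
    bt = with_seed(seed,
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1L),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = hp$nrounds, verbose = 0)),
    gmm = list(pos = fit_class_density(x[y == 1L, , drop = FALSE], hp$components),
               neg = fit_class_density(x[y == 0L, , drop = FALSE], hp$components),
               log_prior_ratio = log(sum(y == 1L) / sum(y == 0L))))
  structure(list(kind = kind, hyperparams = hp, fit = fit,
                 d = ncol(x), seed = as.integer(seed),
                 operating_threshold = NA_real_),
            class = "phyto_classifier")
}

#' Score descriptors with a trained classifier
#'
#' Returns one finite real score per row, a monotone transform of the
#' model's confidence that the row is phytoplankton.
#'
#' @param model A [train_classifier()] model.
#' @param descriptors `n x d` matrix.
#' @return Numeric vector of length `n`.
#' @export
predict_scores <- function(model, descriptors) {
  stopifnot(inherits(model, "phyto_classifier"))
  x <- as.matrix(descriptors)
  if (ncol(x) != model$d)
    stop("descriptor dimension ", ncol(x), " does not match training (",
         model$d, ")", call. = FALSE)
  scores <- switch(model$kind,
    rf = stats::predict(model$fit, x, type = "prob")[, "1"],
    svm = {
      dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    },
    knn = {
      pred <- with_seed(model$seed,
        class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k,
                   prob = TRUE))
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    bt = stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1L)),
    gmm = class_logdens(model$fit$pos, x) - class_logdens(model$fit$neg, x) +
          model$fit$log_prior_ratio)
  as.numeric(scores)
}

#' Operating threshold for a target recall
#'
#' Scans every distinct score as a candidate threshold (predict positive
#' iff `score >= t`) and returns the threshold whose recall reaches
#' `target_recall` with maximal precision; among precision ties the highest
#' threshold wins. Recall 1 is always reachable at the minimum score, so a
#' threshold always exists.
#'
#' @param scores Numeric scores, higher = more phytoplankton-like.
#' @param labels 0/1 labels, both classes present.
#' @param target_recall Required recall in (0, 1].
#' @return The chosen threshold, with the achieved `precision` and `recall`
#'   as attributes.
#' @export
choose_operating_threshold <- function(scores, labels, target_recall = 0.9) {
  stopifnot(length(scores) == length(labels), any(labels == 1), any(labels == 0))
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  best <- NULL
  for (t in th) {
    sel <- scores >= t
    rec <- sum(labels[sel] == 1) / npos
    if (rec >= target_recall) {
      prec <- sum(labels[sel] == 1) / sum(sel)
      if (is.null(best) || prec > best$precision)
        best <- list(threshold = t, precision = prec, recall = rec)
    }
  }
  structure(best$threshold, precision = best$precision, recall = best$recall)
}

#' Precision at a target recall
#'
#' @inheritParams choose_operating_threshold
#' @return Precision achieved at the [choose_operating_threshold()]
#'   operating point.
#' @export
precision_at_recall <- function(scores, labels, target_recall = 0.9) {
  attr(choose_operating_threshold(scores, labels, target_recall), "precision")
}

# Deterministic stratified fold assignment: a function of (seed, labels)
# only. Within each class, indices are permuted under the seed and dealt
# round-robin to folds.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- with_seed(derive_seed(seed, "folds", as.integer(cl)),
                     sample(idx))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}
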