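# Detection and classification metrics.
#
# A detection matches a ground-truth box when it overlaps at least 50% of
# the true box's area (measured against the ground-truth area, not IoU).
# The candidate stage is judged by its false negative rate over
# phytoplankton ground truth; segmentation quality by the over- and
# undersegmentation rates; the classifier by precision-recall curves and
# precision at fixed recall.

#' Match detections against ground-truth boxes
#'
#' @param dets List of [bbox()] detections (or a data frame with
#'   `x_min,y_min,x_max,y_max` columns) from one image.
#' @param gts Annotation data frame for the same image.
#' @return A `match_result`: per ground-truth box the matching detection
#'   indices (overlap >= 0.5 of the ground-truth area) and per detection the
#'   matched ground-truth indices, plus the ground-truth labels.
#' @export
match_detections <- function(dets, gts) {
  if (is.data.frame(dets))
    dets <- lapply(seq_len(nrow(dets)), function(i)
      bbox(dets$x_min[i], dets$y_min[i], dets$x_max[i], dets$y_max[i]))
  gt_boxes <- lapply(seq_len(nrow(gts)), function(i)
    bbox(gts$x_min[i], gts$y_min[i], gts$x_max[i], gts$y_max[i]))
  det_of_gt <- lapply(gt_boxes, function(g) {
    hits <- which(vapply(dets, function(d)
      bbox_intersection_area(d, g) >= 0.5 * bbox_area(g), logical(1)))
    hits
  })
  gt_of_det <- lapply(seq_along(dets), function(i)
    which(vapply(det_of_gt, function(h) i %in% h, logical(1))))
  structure(list(det_of_gt = det_of_gt, gt_of_det = gt_of_det,
                 gt_labels = gts$label, n_det = length(dets)),
            class = "match_result")
}

#' Detection-stage metrics from a match result
#'
#' * `fnr` — fraction of phytoplankton ground-truth boxes with no matching
#'   detection.
#' * `oversegmentation_rate` — fraction of ground-truth boxes matched by
#'   two or more detections (one specimen split across detections).
#' * `undersegmentation_rate` — fraction of detections matching two or more
#'   ground-truth boxes (several specimens enclosed by one detection).
#'
#' Denominators: the FNR is taken over phytoplankton ground-truth boxes
#' only (other objects are intentionally detected at the candidate stage),
#' oversegmentation over the full ground-truth box count, and
#' undersegmentation over the detection count. The counts backing each rate
#' are returned so alternative denominator conventions can be formed.
#'
#' @param match A [match_detections()] result, or a list of them (metrics
#'   are then pooled over images).
#' @return List with the three rates and their numerators/denominators.
#' @export
detection_metrics <- function(match) {
  matches <- if (inherits(match, "match_result")) list(match) else match
  n_gt <- 0L; n_phyto <- 0L; miss <- 0L; over <- 0L
  n_det <- 0L; under <- 0L
  for (m in matches) {
    phyto <- m$gt_labels == "phytoplankton"
    n_gt <- n_gt + length(m$det_of_gt)
    n_phyto <- n_phyto + sum(phyto)
    miss <- miss + sum(vapply(m$det_of_gt[phyto], length, integer(1)) == 0L)
    over <- over + sum(vapply(m$det_of_gt, length, integer(1)) >= 2L)
    n_det <- n_det + m$n_det
    under <- under + sum(vapply(m$gt_of_det, length, integer(1)) >= 2L)
  }
  if (n_gt == 0L)
    warning("no ground-truth boxes; rates reported as 0")
  list(fnr = if (n_phyto) miss / n_phyto else 0,
       oversegmentation_rate = if (n_gt) over / n_gt else 0,
       undersegmentation_rate = if (n_det) under / n_det else 0,
       n_gt = n_gt, n_gt_phytoplankton = n_phyto, n_detections = n_det,
       n_missed = miss, n_oversegmented = over, n_undersegmenting = under)
}

#' Precision-recall curve
#'
#' One point per distinct score threshold (predict positive iff
#' `score >= threshold`), ordered by increasing recall (ties by decreasing
#' threshold).
#'
#' @param scores Numeric scores, higher = more phytoplankton-like.
#' @param labels 0/1 labels; both classes must be present.
#' @return Data frame with `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("precision-recall curve needs both classes", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  pts <- t(vapply(th, function(t) {
    sel <- scores >= t
    c(precision = sum(labels[sel] == 1) / sum(sel),
      recall = sum(labels[sel] == 1) / npos)
  }, numeric(2)))
  out <- data.frame(threshold = th, precision = pts[, "precision"],
                    recall = pts[, "recall"])
  out[order(out$recall, -out$threshold), , drop = FALSE]
}

#' Full evaluation report
#'
#' Combines the detection metrics with a PR curve and precision at the
#' requested recall targets, when scores are available.
#'
#' @param match A [match_detections()] result or list of them.
#' @param scores,labels Optional candidate scores and 0/1 labels for the
#'   classification metrics.
#' @param recall_targets Recall levels for the precision-at-recall map.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(match, scores = NULL, labels = NULL,
                              recall_targets = c(0.90, 0.95)) {
  rep <- detection_metrics(match)
  if (!is.null(scores)) {
    rep$pr_curve <- pr_curve(scores, labels)
    rep$precision_at <- vapply(recall_targets, function(r)
      precision_at_recall(scores, labels, r), numeric(1))
    names(rep$precision_at) <- paste0("recall_", recall_targets)
  }
  structure(rep, class = "evaluation_report")
}

#' Label a detections table against annotations
#'
#' Applies the 50%-overlap rule per image: a detection is positive iff it
#' overlaps at least half of some phytoplankton ground-truth box's area.
#'
#' @param detections Data frame with `image_id,x_min,y_min,x_max,y_max`.
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @return Integer 0/1 vector, one element per detection row.
#' @export
label_detections <- function(detections, annotations) {
  out <- integer(nrow(detections))
  for (img in unique(detections$image_id)) {
    sel <- which(detections$image_id == img)
    gts <- annotations[annotations$image_id == img &
                       annotations$label == "phytoplankton", , drop = FALSE]
    if (!nrow(gts)) next
    gt_boxes <- lapply(seq_len(nrow(gts)), function(i)
      bbox(gts$x_min[i], gts$y_min[i], gts$x_max[i], gts$y_max[i]))
    for (i in sel) {
      d <- bbox(detections$x_min[i], detections$y_min[i],
                detections$x_max[i], detections$y_max[i])
      hit <- any(vapply(gt_boxes, function(g)
        bbox_intersection_area(d, g) >= 0.5 * bbox_area(g), logical(1)))
      out[i] <- as.integer(hit)
    }
  }
  out
}
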