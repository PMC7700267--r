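gt_row <- function(x_min, y_min, x_max, y_max, label = "phytoplankton")
  data.frame(image_id = "i", x_min = x_min, y_min = y_min,
             x_max = x_max, y_max = y_max, label = label)

test_that("detections match when they cover half the ground-truth area", {
  gts <- gt_row(0, 0, 10, 20)
  expect_equal(match_detections(list(bbox(0, 0, 10, 20)), gts)$det_of_gt[[1]], 1L)
  # overlap exactly 100/200 = 0.5: inclusive match
  expect_equal(match_detections(list(bbox(0, 0, 10, 10)), gts)$det_of_gt[[1]], 1L)
  # disjoint: no match
  expect_equal(length(match_detections(list(bbox(50, 50, 60, 60)),
                                       gts)$det_of_gt[[1]]), 0L)
})

test_that("detection metrics count misses, over- and under-segmentation", {
  gts <- do.call(rbind, list(gt_row(0, 0, 10, 10), gt_row(20, 0, 30, 10),
                             gt_row(40, 0, 50, 10), gt_row(60, 0, 70, 10)))
  dets <- list(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10), bbox(40, 0, 50, 10))
  m <- match_detections(dets, gts)
  r <- detection_metrics(m)
  expect_equal(r$fnr, 0.25)            # one of four GT unmatched
  expect_equal(r$oversegmentation_rate, 0)
  expect_equal(r$undersegmentation_rate, 0)

  # every GT matched exactly once: all rates zero
  dets4 <- c(dets, list(bbox(60, 0, 70, 10)))
  r4 <- detection_metrics(match_detections(dets4, gts))
  expect_equal(unlist(r4[c("fnr", "oversegmentation_rate",
                           "undersegmentation_rate")]),
               c(fnr = 0, oversegmentation_rate = 0,
                 undersegmentation_rate = 0))

  # one detection covering two GT boxes among five detections: under = 0.2
  gts2 <- rbind(gt_row(0, 0, 10, 10), gt_row(12, 0, 22, 10))
  dets5 <- list(bbox(0, 0, 22, 10), bbox(30, 0, 40, 10), bbox(50, 0, 60, 10),
                bbox(70, 0, 80, 10), bbox(90, 0, 100, 10))
  r5 <- detection_metrics(match_detections(dets5, gts2))
  expect_equal(r5$undersegmentation_rate, 0.2)

  # two detections on one GT box: oversegmentation
  gts3 <- gt_row(0, 0, 20, 10)
  dets6 <- list(bbox(0, 0, 10, 10), bbox(10, 0, 20, 10))
  r6 <- detection_metrics(match_detections(dets6, gts3))
  expect_equal(r6$oversegmentation_rate, 1)

  expect_warning(detection_metrics(match_detections(dets, gts[0, ])),
                 "no ground-truth")
})

test_that("metrics are invariant to detection and ground-truth ordering", {
  set.seed(17)
  gts <- do.call(rbind, lapply(1:6, function(i)
    gt_row(10 * i, 0, 10 * i + 8, 8,
           label = sample(c("phytoplankton", "other"), 1))))
  dets <- lapply(1:5, function(i) bbox(10 * i, 0, 10 * i + 8, 8))
  r1 <- detection_metrics(match_detections(dets, gts))
  r2 <- detection_metrics(match_detections(rev(dets), gts[sample(6), ]))
  expect_equal(r1[c("fnr", "oversegmentation_rate", "undersegmentation_rate")],
               r2[c("fnr", "oversegmentation_rate", "undersegmentation_rate")])
})

test_that("the PR curve enumerates thresholds and matches the oracle", {
  pr <- pr_curve(c(3, 2, 1), c(1, 0, 1))
  expect_equal(pr$recall, c(1 / 2, 1 / 2, 1))
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3))

  # perfectly separated scores: precision pinned at 1
  pr2 <- pr_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_true(all(pr2$precision[pr2$threshold >= 3] == 1))

  # mirror symmetry: flipping labels and negating scores swaps the classes
  s <- c(0.9, 0.6, 0.4, 0.2); l <- c(1, 0, 1, 0)
  a <- pr_curve(s, l)
  b <- pr_curve(-s, 1 - l)
  expect_equal(max(a$recall), max(b$recall))

  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:50, 1)
    scores <- round(runif(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- pr_curve(scores, labels)
    want <- oracle_pr_points(scores, labels)
    want <- want[order(want$recall, -want$threshold), ]
    expect_equal(got$precision, want$precision, info = paste("seed", seed))
    expect_equal(got$recall, want$recall, info = paste("seed", seed))
  }
  expect_error(pr_curve(c(1, 2), c(1, 1)), "both classes")
})

test_that("FNR complements the matched fraction over phytoplankton boxes", {
  set.seed(23)
  gts <- do.call(rbind, lapply(1:8, function(i) gt_row(20 * i, 0, 20 * i + 10, 10)))
  dets <- lapply(sample(1:8, 5), function(i) bbox(20 * i, 0, 20 * i + 10, 10))
  r <- detection_metrics(match_detections(dets, gts))
  matched <- sum(vapply(match_detections(dets, gts)$det_of_gt, length,
                        integer(1)) > 0)
  expect_equal(r$fnr + matched / 8, 1)
})

test_that("evaluation reports bundle rates with precision-at-recall", {
  gts <- gt_row(0, 0, 10, 10)
  dets <- list(bbox(0, 0, 10, 10))
  rep <- evaluation_report(match_detections(dets, gts),
                           scores = c(3, 2, 1), labels = c(1, 1, 0))
  expect_equal(rep$fnr, 0)
  expect_equal(unname(rep$precision_at["recall_0.9"]), 1)
  expect_s3_class(rep$pr_curve, "data.frame")
})
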