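test_that("matching implements the TP/FP/FN rule at IoU 0.5", {
  gt <- gt_row("f", "A", 0, 0, 10, 10)
  # IoU 0.6 with correct class -> TP
  det <- det_row("f", "A", 0.9, 0, 0, 10, 8)  # IoU 80/100 = 0.8
  m <- classify_predictions(gt, det)
  expect_equal(m$tallies[m$tallies$class == "A", c("TP", "FP", "FN")],
               data.frame(TP = 1L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  # same geometry, wrong class -> FP for B, FN for A
  det2 <- det_row("f", "B", 0.9, 0, 0, 10, 8)
  m2 <- classify_predictions(gt, det2,
                             eval_config(catalog = class_catalog(c("A", "B"))))
  t2 <- m2$tallies
  expect_equal(t2$FP[t2$class == "B"], 1L)
  expect_equal(t2$FN[t2$class == "A"], 1L)
  # a tie at exactly the threshold counts as matching (>=)
  det3 <- det_row("f", "A", 0.9, 0, 0, 10, 5)  # IoU exactly 0.5
  m3 <- classify_predictions(gt, det3)
  expect_equal(m3$detections$status, "TP")
})

test_that("duplicate hits on one ground truth count as FPs", {
  gt <- gt_row("f", "A", 0, 0, 10, 10)
  det <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 9),
               det_row("f", "A", 0.8, 0, 0, 10, 8))
  m <- classify_predictions(gt, det)
  expect_equal(m$detections$status, c("TP", "FP"))
  # the higher-confidence detection claims the instance
  expect_equal(m$detections$matched_gt_id[1], m$gt$gt_id[1])
  t <- m$tallies
  expect_equal(t[t$class == "A", c("TP", "FP", "FN")],
               data.frame(TP = 1L, FP = 1L, FN = 0L), ignore_attr = TRUE)
})

test_that("TP + FN equals ground truth per class on random scenes", {
  cfg <- scene_config(c("A", "B"), n_frames = 20, rate = 2, seed = 11)
  sc <- generate_scenes(cfg)
  em <- error_model(c("A", "B"), miss_rate = 0.3, clutter_rate = 1,
                    jitter = 0.1, seed = 5)
  det <- corrupt(sc$annotations, em)$detections
  m <- classify_predictions(sc$annotations, det)
  for (i in seq_len(nrow(m$tallies))) {
    expect_equal(m$tallies$TP[i] + m$tallies$FN[i], m$tallies$n_gt[i])
  }
  # each ground truth matched at most once
  ids <- m$detections$matched_gt_id
  expect_false(anyDuplicated(ids[!is.na(ids)]) > 0)
})

test_that("precision/recall/F1 reproduce the printed-table identity", {
  prf <- precision_recall_f1(801, 109, 199)  # REC 80.1%, PREC 88.0%
  expect_equal(round(unname(prf["recall"]), 1), 80.1)
  expect_equal(round(unname(prf["precision"]), 1), 88.0)
  expect_equal(round(unname(prf["f1"]), 1), 83.9)
  expect_equal(unname(precision_recall_f1(5, 5, 5)),
               c(50, 50, 50))
  expect_equal(unname(precision_recall_f1(0, 0, 3)), c(0, 0, 0))
})

test_that("AP matches hand-derived envelope values", {
  # perfect detector
  gt <- rbind(gt_row("f", "A", 0, 0, 10, 10),
              gt_row("f", "A", 20, 20, 30, 30))
  det <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 10),
               det_row("f", "A", 0.8, 20, 20, 30, 30))
  ev <- evaluate_detections(gt, det)
  expect_equal(ev$per_class$AP, 100)
  expect_equal(ev$mAP, 100)
  # ranked outcomes [TP, FP, TP] with 2 GT -> 83.33%
  det2 <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 10),
                det_row("f", "A", 0.8, 50, 50, 60, 60),
                det_row("f", "A", 0.7, 20, 20, 30, 30))
  ev2 <- evaluate_detections(gt, det2)
  expect_equal(ev2$per_class$AP, 100 * 5 / 6, tolerance = 1e-10)
  # no detections of a class with ground truth -> AP 0
  ev3 <- evaluate_detections(gt, det2[0, ])
  expect_equal(ev3$per_class$AP, 0)
})

test_that("AP equals the brute-force rectangle-sum oracle on random runs", {
  set.seed(13)
  for (rep in 1:200) {
    n_det <- sample.int(20, 1)
    n_gt <- sample.int(10, 1)
    is_tp <- runif(n_det) < 0.5
    # at most n_gt TPs possible
    if (sum(is_tp) > n_gt) is_tp[which(is_tp)[-seq_len(n_gt)]] <- FALSE
    expect_equal(jellyeval:::ap_envelope(is_tp, n_gt),
                 ap_rectangle_oracle(is_tp, n_gt))
  }
})

test_that("AP is rank-only: invariant to monotone confidence rescaling", {
  cfg <- scene_config(c("A", "B"), n_frames = 15, rate = 2, seed = 21)
  sc <- generate_scenes(cfg)
  em <- error_model(c("A", "B"), miss_rate = 0.2, clutter_rate = 1,
                    jitter = 0.05, seed = 9)
  det <- corrupt(sc$annotations, em)$detections
  ev1 <- evaluate_detections(sc$annotations, det)
  det2 <- det
  det2$confidence <- det$confidence^3  # strictly monotone on [0, 1]
  ev2 <- evaluate_detections(sc$annotations, det2)
  expect_equal(ev1$per_class$AP, ev2$per_class$AP)
})

test_that("appending a lowest-confidence FP never increases AP", {
  gt <- rbind(gt_row("f", "A", 0, 0, 10, 10),
              gt_row("f", "A", 20, 20, 30, 30),
              gt_row("f", "A", 40, 40, 50, 50))
  det <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 10),
               det_row("f", "A", 0.6, 20, 20, 30, 30))
  base <- evaluate_detections(gt, det)$per_class$AP
  worse <- rbind(det, det_row("f", "A", 0.1, 70, 70, 80, 80))
  after <- evaluate_detections(gt, worse)$per_class$AP
  expect_lte(after, base)
})

test_that("mAP is the unweighted mean and reproduces printed region values", {
  expect_equal(round(mean_ap(c(82.5, 99.3, 83.4, 99.5, 91.6, 78.1, 96.0)), 1),
               90.1)
  expect_equal(round(mean_ap(c(82.4, 96.9, 97.5, 79.2)), 1), 89.0)
  expect_equal(mean_ap(c(70, 70, 70)), 70)
  expect_equal(mean_ap(c(50, NA, 100)), 75)  # undefined classes excluded
  expect_error(mean_ap(numeric(0)), "no class")
})

test_that("class without ground truth has absent (NA) AP, not zero", {
  gt <- gt_row("f", "A", 0, 0, 10, 10)
  det <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 10),
               det_row("f", "B", 0.5, 50, 50, 60, 60))
  ev <- evaluate_detections(gt, det)
  expect_true(is.na(ev$per_class$AP[ev$per_class$class == "B"]))
  expect_equal(ev$mAP, 100)  # mean over defined classes only
})
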