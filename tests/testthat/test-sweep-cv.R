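test_that("sweep separates TPs from FPs at the planted threshold", {
  gt <- rbind(gt_row("f", "A", 0, 0, 10, 10),
              gt_row("f", "A", 20, 20, 30, 30),
              gt_row("f", "A", 40, 40, 50, 50))
  det <- rbind(det_row("f", "A", 0.60, 0, 0, 10, 10),
               det_row("f", "A", 0.75, 20, 20, 30, 30),
               det_row("f", "A", 0.90, 40, 40, 50, 50),
               det_row("f", "A", 0.599, 70, 70, 80, 80),  # FP
               det_row("f", "A", 0.30, 70, 0, 80, 10))    # FP
  sw <- threshold_sweep(gt, det)
  expect_equal(sw$selected$c_thr, 60)
  expect_equal(sw$selected$f1, 100)
  # all TPs at c_thr 0 -> F1 < 100 because FPs survive
  expect_lt(sw$grid$f1[sw$grid$c_thr == 0], 100)
})

test_that("an all-TP detection set selects C_thr 0 by the tie-break", {
  gt <- rbind(gt_row("f", "A", 0, 0, 10, 10),
              gt_row("f", "A", 20, 20, 30, 30))
  det <- rbind(det_row("f", "A", 0.9, 0, 0, 10, 10),
               det_row("f", "A", 0.7, 20, 20, 30, 30))
  sw <- threshold_sweep(gt, det)
  expect_equal(sw$selected$c_thr, 0)
  expect_equal(sw$selected$f1, 100)
})

test_that("sweep agrees with the exhaustive per-step re-matching oracle", {
  cfg <- scene_config(c("A", "B"), n_frames = 20, rate = 1.5, seed = 41)
  sc <- generate_scenes(cfg)
  em <- error_model(c("A", "B"), miss_rate = 0.2, clutter_rate = 1,
                    jitter = 0.12, seed = 6)
  det <- corrupt(sc$annotations, em)$detections
  sw <- threshold_sweep(sc$annotations, det)
  oracle <- naive_sweep_oracle(sc$annotations, det)
  expect_equal(sw$grid$precision, oracle$precision, tolerance = 1e-12)
  expect_equal(sw$grid$recall, oracle$recall, tolerance = 1e-12)
  expect_equal(sw$grid$f1, oracle$f1, tolerance = 1e-12)
  # selected F1 is the grid maximum, ties broken toward the lowest C_thr
  expect_equal(sw$selected$f1, max(oracle$f1))
  expect_equal(sw$selected$c_thr,
               min(oracle$c_thr[oracle$f1 == max(oracle$f1)]))
  # recall is non-increasing along the grid; step 0 equals unswept metrics
  expect_true(all(diff(sw$grid$recall) <= 1e-12))
  m0 <- precision_recall_f1(classify_predictions(sc$annotations, det))
  expect_equal(sw$grid$f1[1], unname(m0["f1"]))
})

test_that("empty detection set yields a degenerate flagged sweep", {
  gt <- gt_row("f", "A", 0, 0, 10, 10)
  det <- det_row("f", "A", 0.5, 0, 0, 1, 1)[0, ]
  sw <- threshold_sweep(gt, det)
  expect_true(sw$degenerate)
  expect_true(all(sw$grid$f1 == 0))
  expect_equal(sw$selected$c_thr, 0)
})

test_that("folds partition the frames with sizes differing by at most one", {
  frames <- sprintf("f%03d", 1:100)
  f5 <- make_folds(frames, k = 5, seed = 3)
  sizes <- table(f5$assignment$fold)
  expect_equal(unname(as.integer(sizes)), rep(20L, 5))
  expect_setequal(f5$assignment$frame_id, frames)

  f103 <- make_folds(sprintf("f%03d", 1:103), k = 5, seed = 3)
  expect_equal(sort(as.integer(table(f103$assignment$fold)),
                    decreasing = TRUE), c(21L, 21L, 21L, 20L, 20L))
  # determinism
  f5b <- make_folds(frames, k = 5, seed = 3)
  expect_equal(f5$assignment, f5b$assignment)
  f5c <- make_folds(frames, k = 5, seed = 4)
  expect_false(identical(f5$assignment, f5c$assignment))
  expect_error(make_folds(frames[1:3], k = 5), "k")
})

test_that("stratified folds spread strata while keeping sizes balanced", {
  frames <- sprintf("f%03d", 1:60)
  strata <- rep(c("A", "B", "C"), each = 20)
  f <- make_folds(frames, k = 5, seed = 7, strata = strata)
  expect_equal(unname(as.integer(table(f$assignment$fold))), rep(12L, 5))
  byfold <- table(strata[match(f$assignment$frame_id, frames)],
                  f$assignment$fold)
  expect_true(all(byfold == 4L))
})

test_that("fold aggregation averages metrics and handles absent classes", {
  mk <- function(f1, ap_a, ap_b = NA) {
    structure(list(region = "R",
                   per_class = data.frame(class = c("A", "B"),
                                          AP = c(ap_a, ap_b)),
                   mAP = mean(c(ap_a, ap_b), na.rm = TRUE), c_thr = 50,
                   recall = 80, precision = 90, f1 = f1),
              class = "jf_report")
  }
  reps <- list(mk(80, 70, 90), mk(85, 80, 90), mk(90, 90, 90),
               mk(75, 60, NA), mk(95, 100, NA))
  agg <- aggregate_folds(reps)
  expect_equal(agg$f1, 85)
  expect_equal(agg$per_class$AP[agg$per_class$class == "A"], 80)
  # class B defined in 3 of 5 folds: mean over defined folds, coverage kept
  expect_equal(agg$per_class$AP[agg$per_class$class == "B"], 90)
  expect_equal(agg$per_class$n_folds, c(5, 3))
  # permutation invariance
  agg2 <- aggregate_folds(rev(reps))
  expect_equal(agg$per_class, agg2$per_class)
  expect_equal(agg$mAP, agg2$mAP)
  # identical reports aggregate to themselves
  same <- aggregate_folds(list(mk(80, 70, 90), mk(80, 70, 90)))
  expect_equal(same$f1, 80)
  expect_equal(same$per_class$AP, c(70, 90))
  bad <- mk(80, 70, 90); bad$per_class$class <- c("A", "Z")
  expect_error(aggregate_folds(list(mk(80, 70, 90), bad)), "mismatched")
})

test_that("the k-fold harness is reproducible and covers every frame once", {
  cfg <- scene_config(c("A", "B"), n_frames = 30, rate = 1.5, seed = 43)
  sc <- generate_scenes(cfg)
  em <- error_model(c("A", "B"), miss_rate = 0.2, clutter_rate = 0.5,
                    seed = 8)
  detector <- synthetic_detector(sc$annotations, em)
  r1 <- kfold_evaluate(sc$annotations, detector, k = 5, seed = 2)
  r2 <- kfold_evaluate(sc$annotations, detector, k = 5, seed = 2)
  expect_equal(r1$aggregate$mAP, r2$aggregate$mAP)
  expect_equal(r1$folds$assignment, r2$folds$assignment)
  tested <- unlist(lapply(1:5, function(i) fold_frames(r1$folds, i)))
  expect_setequal(tested, unique(sc$annotations$frame_id))
  expect_equal(anyDuplicated(tested), 0L)
  expect_equal(r1$aggregate$mAP,
               mean(vapply(r1$reports, `[[`, 0, "mAP")))
})
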