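test_that("scene generation is seeded, rate-faithful and in-frame", {
  cfg <- scene_config(c("A", "B"), n_frames = 40, rate = 2, seed = 71)
  sc1 <- generate_scenes(cfg)
  sc2 <- generate_scenes(cfg)
  expect_equal(sc1$annotations, sc2$annotations, ignore_attr = TRUE)
  expect_equal(sc1$manifest$timestamp_s, (0:39) * 5)  # 5 s stride
  expect_true(all(sc1$annotations$xmin >= 0 & sc1$annotations$ymin >= 0))
  expect_true(all(sc1$annotations$xmax <= 1280 &
                    sc1$annotations$ymax <= 720))
  # zero rate -> every frame empty
  sc0 <- generate_scenes(scene_config(c("A"), n_frames = 10, rate = 0,
                                      seed = 1))
  expect_equal(nrow(sc0$annotations), 0L)
  # Poisson rate recovered within 3 sigma at 1000 frames
  scp <- generate_scenes(scene_config("A", n_frames = 1000, rate = 3,
                                      seed = 72, side_range = c(10, 40)))
  mean_per_frame <- nrow(scp$annotations) / 1000
  expect_lt(abs(mean_per_frame - 3), 3 * sqrt(3 / 1000))
})

test_that("bloom mode produces overlapping aggregations", {
  base <- scene_config("A", n_frames = 30, rate = 4, seed = 73)
  bloom <- scene_config("A", n_frames = 30, rate = 4, bloom = TRUE,
                        seed = 73)
  overlap_frac <- function(sc) {
    per_frame <- split(sc$annotations, sc$annotations$frame_id)
    hits <- vapply(per_frame, function(f) {
      if (nrow(f) < 2) return(0)
      m <- iou_matrix(f, f); diag(m) <- 0
      mean(m > 0)
    }, 0)
    mean(hits)
  }
  expect_gt(overlap_frac(generate_scenes(bloom)),
            overlap_frac(generate_scenes(base)))
})

test_that("an all-zero error model echoes ground truth with perfect AP", {
  sc <- generate_scenes(scene_config(c("A", "B"), n_frames = 20, rate = 2,
                                     seed = 74))
  out <- corrupt(sc$annotations, error_model(c("A", "B"), seed = 1))
  expect_equal(nrow(out$detections), nrow(sc$annotations))
  expect_equal(out$detections[, c("frame_id", "species", "xmin", "ymin",
                                  "xmax", "ymax")],
               sc$annotations[order(sc$annotations$frame_id),
                              c("frame_id", "species", "xmin", "ymin",
                                "xmax", "ymax")],
               ignore_attr = TRUE)
  ev <- evaluate_detections(sc$annotations, out$detections)
  expect_equal(ev$per_class$AP, c(100, 100))
  # miss rate 1 -> empty detections
  gone <- corrupt(sc$annotations, error_model(c("A", "B"), miss_rate = 1,
                                              seed = 1))
  expect_equal(nrow(gone$detections), 0L)
  # non-stochastic confusion row is rejected
  badconf <- matrix(c(0.5, 0.4, 0, 1), 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(error_model(c("A", "B"), confusion = badconf), "stochastic")
})

test_that("evaluation recovers planted miss and clutter rates", {
  sc <- generate_scenes(scene_config(c("A", "B"), n_frames = 700, rate = 2,
                                     seed = 75))
  em <- error_model(c("A", "B"), miss_rate = 0.3, clutter_rate = 0.8,
                    seed = 2)
  out <- corrupt(sc$annotations, em)
  m <- classify_predictions(sc$annotations, out$detections)
  n_gt <- sum(m$tallies$n_gt)
  expect_gte(n_gt, 2000)
  fn_rate <- sum(m$tallies$FN) / n_gt
  ci <- stats::qbinom(c(0.025, 0.975), n_gt, 0.3) / n_gt
  expect_gte(fn_rate, ci[1]); expect_lte(fn_rate, ci[2])
  # clutter count ~ Poisson(rate * frames)
  n_clutter <- sum(out$log$source == "clutter")
  lam <- 0.8 * 700
  expect_lt(abs(n_clutter - lam), 4 * sqrt(lam))
  # clutter never matches ground truth by construction odds: all FPs come
  # from the log's clutter + any jittered-away instances (jitter 0 here)
  expect_equal(sum(m$tallies$FP), n_clutter)
})

test_that("detection quality degrades monotonically with miss and jitter", {
  sc <- generate_scenes(scene_config(c("A", "B"), n_frames = 150, rate = 2,
                                     seed = 76))
  map_at <- function(miss = 0, jitter = 0) {
    em <- error_model(c("A", "B"), miss_rate = miss, jitter = jitter,
                      seed = 3)
    det <- corrupt(sc$annotations, em)$detections
    if (nrow(det) == 0) return(0)
    evaluate_detections(sc$annotations, det)$mAP
  }
  by_miss <- vapply(c(0, 0.3, 0.6, 0.9), function(m) map_at(miss = m), 0)
  expect_true(all(diff(by_miss) <= 1e-9))
  by_jitter <- vapply(c(0, 0.1, 0.3, 0.6), function(j) map_at(jitter = j), 0)
  expect_true(all(diff(by_jitter) <= 1e-9))
})

test_that("the synthetic detector contract is batching-invariant", {
  sc <- generate_scenes(scene_config(c("A", "B"), n_frames = 12, rate = 2,
                                     seed = 77))
  em <- error_model(c("A", "B"), miss_rate = 0.2, clutter_rate = 0.5,
                    jitter = 0.05, seed = 4)
  detector <- synthetic_detector(sc$annotations, em)
  frames <- sc$manifest$frame_id
  whole <- detector(frames)
  pieces <- do.call(rbind, lapply(frames, detector))
  ord <- function(d) {
    d <- d[order(d$frame_id, d$confidence), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(whole), ord(pieces))
})

test_that("separating lookalike species by region removes their confusion", {
  # two lookalike species with heavy mutual confusion but disjoint ranges:
  # region 1 footage contains only A, region 2 footage only B
  sc1 <- generate_scenes(scene_config("A", n_frames = 150, rate = 2,
                                      video_id = "region1", seed = 81))
  sc2 <- generate_scenes(scene_config("B", n_frames = 150, rate = 2,
                                      video_id = "region2", seed = 82))
  sc2$annotations$frame_id <- sub("frame_", "frame_r2_",
                                  sc2$annotations$frame_id)
  gt <- rbind(sc1$annotations, sc2$annotations)
  attr(gt, "frame_width") <- 1280; attr(gt, "frame_height") <- 720
  confusion <- matrix(c(0.65, 0.35, 0.35, 0.65), 2, byrow = TRUE,
                      dimnames = list(c("A", "B"), c("A", "B")))
  em <- error_model(c("A", "B"), confusion = confusion, seed = 5)
  det <- corrupt(gt, em)$detections
  stopifnot(sum(det$species != "A" & det$frame_id %in%
                  sc1$annotations$frame_id) > 0)

  # pooled single-catalog evaluation
  pooled_cfg <- eval_config(catalog = class_catalog(c("A", "B")))
  pooled_ev <- evaluate_detections(gt, det, pooled_cfg)
  pooled_cm <- confusion_matrix(gt, det, pooled_cfg)
  pooled_off <- (sum(pooled_cm$counts) - sum(diag(pooled_cm$counts))) /
    sum(pooled_cm$counts)

  # per-region evaluation: each region's frames with its own 1-species
  # catalog; out-of-catalog labels are filtered, as a regional model that
  # cannot emit them
  eval_region <- function(frames, species) {
    g <- gt[gt$frame_id %in% frames, , drop = FALSE]
    d <- det[det$frame_id %in% frames & det$species %in% species, ,
             drop = FALSE]
    cfg <- eval_config(catalog = class_catalog(species))
    list(ev = evaluate_detections(g, d, cfg),
         cm = confusion_matrix(g, d, cfg))
  }
  r1 <- eval_region(unique(sc1$annotations$frame_id), "A")
  r2 <- eval_region(unique(sc2$annotations$frame_id), "B")
  off_diag <- function(cm) {
    (sum(cm$counts) - sum(diag(cm$counts))) / sum(cm$counts)
  }
  # strictly less confusion and strictly higher per-class AP per region
  expect_gt(pooled_off, 0)
  expect_lt(off_diag(r1$cm), pooled_off)
  expect_lt(off_diag(r2$cm), pooled_off)
  ap_pooled <- pooled_ev$per_class$AP
  expect_gt(r1$ev$per_class$AP,
            ap_pooled[pooled_ev$per_class$class == "A"])
  expect_gt(r2$ev$per_class$AP,
            ap_pooled[pooled_ev$per_class$class == "B"])
})

test_that("synthetic datasets round-trip through the standard file dialects", {
  dir <- tempfile()
  res <- cmd_simulate(dir, classes = "A,B", n_frames = 8, rate = 1.5,
                      miss_rate = 0.2, clutter_rate = 0.5, seed = 6)
  voc <- read_voc_dir(file.path(dir, "annotations"))
  expect_equal(nrow(voc$annotations), nrow(res$scenes$annotations))
  det <- read_detections(file.path(dir, "detections.csv"))
  expect_equal(nrow(det), nrow(res$corrupted$detections))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8L)
  log <- utils::read.csv(file.path(dir, "truth_log.csv"))
  expect_equal(nrow(log), nrow(det))
  unlink(dir, recursive = TRUE)
})
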