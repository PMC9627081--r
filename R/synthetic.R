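# Synthetic scenes and an imperfect synthetic detector with a known,
# logged error structure. The generator stands in for video-derived frame
# sequences (fixed-stride extraction, default one frame every 5 s); the
# error model plants misses, label confusions, localization jitter and
# background clutter whose rates the evaluation modules must recover.
#
# Randomness: a global seed plus per-frame substreams (each frame reseeds
# from a hash of the global seed and the frame index), so generation is
# reproducible regardless of how frames are batched. Within corrupt(),
# draws are staged per frame (all miss draws, then all jitter draws, then
# labels, then confidences) so that changing one rate leaves the other
# stages' draws untouched; detection sets at nested miss rates are then
# themselves nested.

frame_substream_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}

#' Synthetic scene configuration
#'
#' @param classes Character vector of species labels (at least one).
#' @param n_frames Number of frames (default 50).
#' @param frame_width,frame_height Frame size in pixels (default 1280 x
#'   720).
#' @param rate Mean instances per frame and class (Poisson); scalar or
#'   named per-class vector. Default 1.
#' @param bloom Place instances in overlapping spatial clusters, emulating
#'   aggregations of bloom-forming species? Default `FALSE` (instances are
#'   placed uniformly).
#' @param side_range Box side lengths drawn uniformly from this range in
#'   pixels (default 40..160; minimum 2).
#' @param stride_s Manifest timestamp stride in seconds (default 5).
#' @param video_id Manifest video id.
#' @param seed Integer seed.
#' @return List of class `jf_scene_config`.
#' @export
scene_config <- function(classes, n_frames = 50, frame_width = 1280,
                         frame_height = 720, rate = 1, bloom = FALSE,
                         side_range = c(40, 160), stride_s = 5,
                         video_id = "synthetic", seed = 1) {
  classes <- as.character(class_catalog(classes))
  if (length(rate) == 1L && is.null(names(rate))) {
    rate <- stats::setNames(rep(rate, length(classes)), classes)
  }
  if (!all(classes %in% names(rate)) || any(rate < 0)) {
    stop("scene_config: rate must be non-negative, scalar or named for ",
         "every class", call. = FALSE)
  }
  if (side_range[1] < 2 || side_range[2] < side_range[1]) {
    stop("scene_config: box sides must be at least 2 px", call. = FALSE)
  }
  if (side_range[2] > min(frame_width, frame_height)) {
    stop("scene_config: box sides exceed the frame", call. = FALSE)
  }
  structure(list(classes = classes, n_frames = n_frames,
                 frame_width = frame_width, frame_height = frame_height,
                 rate = rate[classes], bloom = bloom,
                 side_range = side_range, stride_s = stride_s,
                 video_id = video_id, seed = seed),
            class = "jf_scene_config")
}

#' Generate synthetic ground-truth scenes
#'
#' Per frame and class, an instance count is drawn from a Poisson with the
#' configured rate; boxes get integer corner coordinates, uniform sides
#' within `side_range`, and are placed uniformly (or, in bloom mode, around
#' a per-frame cluster center with Gaussian scatter of half a box side, so
#' instances overlap). Boxes always lie inside the frame. Reproducible
#' given the seed.
#'
#' @param cfg A [scene_config()].
#' @return List with `annotations` (ground-truth table with `gt_id`s),
#'   `manifest` (fixed-stride timestamps), and `frames` (frame_id, width,
#'   height). The frame size is attached to the annotations as attributes
#'   `frame_width`/`frame_height`.
#' @export
generate_scenes <- function(cfg) {
  stopifnot(inherits(cfg, "jf_scene_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  w <- cfg$frame_width; h <- cfg$frame_height
  rows <- vector("list", cfg$n_frames)
  frame_ids <- sprintf("frame_%06d", seq_len(cfg$n_frames))
  for (i in seq_len(cfg$n_frames)) {
    set.seed(frame_substream_seed(cfg$seed, i))
    counts <- stats::rpois(length(cfg$classes), cfg$rate)
    n <- sum(counts)
    if (n == 0L) next
    species <- rep(cfg$classes, counts)
    sw <- round(stats::runif(n, cfg$side_range[1], cfg$side_range[2]))
    sh <- round(stats::runif(n, cfg$side_range[1], cfg$side_range[2]))
    if (cfg$bloom) {
      cx0 <- stats::runif(1, 0.25 * w, 0.75 * w)
      cy0 <- stats::runif(1, 0.25 * h, 0.75 * h)
      cx <- stats::rnorm(n, cx0, mean(sw) / 2)
      cy <- stats::rnorm(n, cy0, mean(sh) / 2)
    } else {
      cx <- stats::runif(n, 0, w)
      cy <- stats::runif(n, 0, h)
    }
    xmin <- pmin(pmax(round(cx - sw / 2), 0), w - sw)
    ymin <- pmin(pmax(round(cy - sh / 2), 0), h - sh)
    rows[[i]] <- data.frame(frame_id = frame_ids[i], species = species,
                            xmin = xmin, ymin = ymin,
                            xmax = xmin + sw, ymax = ymin + sh,
                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  if (is.null(ann)) {
    ann <- data.frame(frame_id = character(0), species = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      stringsAsFactors = FALSE)
  }
  ann <- as_annotations(ann)
  attr(ann, "frame_width") <- w
  attr(ann, "frame_height") <- h
  manifest <- as_manifest(data.frame(
    video_id = cfg$video_id, frame_id = frame_ids,
    timestamp_s = (seq_len(cfg$n_frames) - 1) * cfg$stride_s,
    stringsAsFactors = FALSE))
  list(annotations = ann, manifest = manifest,
       frames = data.frame(frame_id = frame_ids, width = w, height = h,
                           stringsAsFactors = FALSE))
}

#' Synthetic detector error model
#'
#' @param classes Character vector of species labels the detector can emit.
#' @param miss_rate Per-class probability that a ground-truth instance goes
#'   undetected (scalar or named per-class). Default 0.
#' @param clutter_rate Expected spurious background detections per frame
#'   (Poisson). Default 0.
#' @param jitter Localization noise: box corners are perturbed by Gaussian
#'   noise with standard deviation `jitter` times the box side (x corners
#'   scale with width, y corners with height). Jittered boxes are clipped
#'   to the frame; a heavily jittered box may fall below IoU 0.5 with its
#'   source and become a false positive, which is intended. Default 0.
#' @param confusion Row-stochastic label-confusion matrix over `classes`
#'   (rows = true species, columns = emitted label; the diagonal is the
#'   correct-label probability). Default: identity.
#' @param conf_correct,conf_wrong Beta shape pairs for detection
#'   confidences of correctly labeled detections (default Beta(8, 2):
#'   high) and of confused or clutter detections (default Beta(2, 4):
#'   low). The separation is what gives a threshold sweep structure to
#'   find.
#' @param seed Integer seed (per-frame substreams as in
#'   [generate_scenes()]).
#' @return List of class `jf_error_model`.
#' @export
error_model <- function(classes, miss_rate = 0, clutter_rate = 0,
                        jitter = 0, confusion = NULL,
                        conf_correct = c(8, 2), conf_wrong = c(2, 4),
                        seed = 1) {
  classes <- as.character(class_catalog(classes))
  k <- length(classes)
  if (length(miss_rate) == 1L && is.null(names(miss_rate))) {
    miss_rate <- stats::setNames(rep(miss_rate, k), classes)
  }
  if (!all(classes %in% names(miss_rate)) ||
      any(miss_rate < 0 | miss_rate > 1)) {
    stop("error_model: miss_rate must lie in [0, 1] for every class",
         call. = FALSE)
  }
  if (clutter_rate < 0) stop("error_model: clutter_rate must be >= 0",
                             call. = FALSE)
  if (jitter < 0) stop("error_model: jitter must be >= 0", call. = FALSE)
  if (is.null(confusion)) {
    confusion <- diag(k)
    dimnames(confusion) <- list(classes, classes)
  }
  confusion <- confusion[classes, classes, drop = FALSE]
  if (any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop("error_model: confusion rows must be stochastic (sum to 1)",
         call. = FALSE)
  }
  structure(list(classes = classes, miss_rate = miss_rate[classes],
                 clutter_rate = clutter_rate, jitter = jitter,
                 confusion = confusion, conf_correct = conf_correct,
                 conf_wrong = conf_wrong, seed = seed),
            class = "jf_error_model")
}

# corrupt one frame's worth of ground truth; staged draws (see file header)
corrupt_frame <- function(gt_f, em, w, h, frame_id, frame_index) {
  set.seed(frame_substream_seed(em$seed, frame_index))
  n <- nrow(gt_f)
  u_miss <- if (n > 0L) stats::runif(n) else numeric(0)
  jx <- if (n > 0L) matrix(stats::rnorm(4 * n), n, 4) else
    matrix(0, 0, 4)
  u_label <- if (n > 0L) stats::runif(n) else numeric(0)
  n_clutter <- stats::rpois(1, em$clutter_rate)

  det <- NULL; log <- NULL
  if (n > 0L) {
    kept <- u_miss >= em$miss_rate[gt_f$species]
    if (any(kept)) {
      g <- gt_f[kept, , drop = FALSE]
      bw <- g$xmax - g$xmin; bh <- g$ymax - g$ymin
      j <- jx[kept, , drop = FALSE] * em$jitter
      xmin <- g$xmin + j[, 1] * bw; xmax <- g$xmax + j[, 2] * bw
      ymin <- g$ymin + j[, 3] * bh; ymax <- g$ymax + j[, 4] * bh
      xmin <- pmin(pmax(xmin, 0), w - 2); ymin <- pmin(pmax(ymin, 0), h - 2)
      xmax <- pmin(pmax(xmax, xmin + 2), w)
      ymax <- pmin(pmax(ymax, ymin + 2), h)
      # emitted label from the species' confusion row (shared uniform draw)
      u_kept <- u_label[kept]
      lab <- vapply(seq_len(nrow(g)), function(i) {
        p <- em$confusion[g$species[i], ]
        idx <- findInterval(u_kept[i], cumsum(p), left.open = TRUE) + 1L
        em$classes[min(idx, length(em$classes))]
      }, "")
      correct <- lab == g$species
      conf <- numeric(nrow(g))
      conf[correct] <- stats::rbeta(sum(correct), em$conf_correct[1],
                                    em$conf_correct[2])
      conf[!correct] <- stats::rbeta(sum(!correct), em$conf_wrong[1],
                                     em$conf_wrong[2])
      det <- data.frame(frame_id = frame_id, species = lab,
                        confidence = conf, xmin = xmin, ymin = ymin,
                        xmax = xmax, ymax = ymax,
                        stringsAsFactors = FALSE)
      log <- data.frame(frame_id = frame_id, source = "gt",
                        gt_id = g$gt_id, true_species = g$species,
                        emitted_species = lab,
                        stringsAsFactors = FALSE)
    }
  }
  if (n_clutter > 0L) {
    side_hi <- c(min(200, w - 1), min(200, h - 1))
    sw <- round(stats::runif(n_clutter, min(20, side_hi[1] / 2), side_hi[1]))
    sh <- round(stats::runif(n_clutter, min(20, side_hi[2] / 2), side_hi[2]))
    xmin <- round(stats::runif(n_clutter, 0, pmax(w - sw, 0)))
    ymin <- round(stats::runif(n_clutter, 0, pmax(h - sh, 0)))
    lab <- em$classes[sample.int(length(em$classes), n_clutter,
                                 replace = TRUE)]
    cdet <- data.frame(frame_id = frame_id, species = lab,
                       confidence = stats::rbeta(n_clutter,
                                                 em$conf_wrong[1],
                                                 em$conf_wrong[2]),
                       xmin = xmin, ymin = ymin, xmax = xmin + sw,
                       ymax = ymin + sh, stringsAsFactors = FALSE)
    clog <- data.frame(frame_id = frame_id, source = "clutter",
                       gt_id = NA_character_,
                       true_species = NA_character_,
                       emitted_species = lab, stringsAsFactors = FALSE)
    det <- rbind(det, cdet)
    log <- rbind(log, clog)
  }
  list(det = det, log = log)
}

#' Corrupt ground truth into synthetic detections
#'
#' Applies the error model to an annotation set: each ground-truth instance
#' is independently missed with its class's miss rate, otherwise emitted
#' with a jittered box, a label drawn from its species' confusion row and a
#' confidence from the matching Beta distribution; per frame, Poisson
#' background clutter is added. The hidden truth of every emitted detection
#' (its source instance or clutter origin, true and emitted label) is
#' returned as an assignment log for oracle tests.
#'
#' @param gt Ground-truth table; frame size is taken from its
#'   `frame_width`/`frame_height` attributes (as set by
#'   [generate_scenes()]) or from `frame_width`/`frame_height`.
#' @param em An [error_model()].
#' @param frames Optional character vector of frame ids to corrupt
#'   (defaults to the frames present in `gt`); frames with no ground truth
#'   still receive clutter.
#' @param frame_width,frame_height Frame size override.
#' @return List with `detections` and `log` (one row per emitted
#'   detection, aligned with `detections`).
#' @export
corrupt <- function(gt, em, frames = NULL, frame_width = NULL,
                    frame_height = NULL) {
  stopifnot(inherits(em, "jf_error_model"))
  gt <- as_annotations(gt)
  check_labels(gt$species, em$classes, "corrupt")
  w <- frame_width %||% attr(gt, "frame_width") %||% 1280
  h <- frame_height %||% attr(gt, "frame_height") %||% 720
  if (is.null(frames)) frames <- sort(unique(gt$frame_id))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- lapply(seq_along(frames), function(i) {
    corrupt_frame(gt[gt$frame_id == frames[i], , drop = FALSE], em, w, h,
                  frames[i], frame_index_of(frames[i], i))
  })
  det <- do.call(rbind, lapply(out, `[[`, "det"))
  log <- do.call(rbind, lapply(out, `[[`, "log"))
  if (is.null(det)) {
    det <- data.frame(frame_id = character(0), species = character(0),
                      confidence = numeric(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0),
                      ymax = numeric(0), stringsAsFactors = FALSE)
    log <- data.frame(frame_id = character(0), source = character(0),
                      gt_id = character(0), true_species = character(0),
                      emitted_species = character(0),
                      stringsAsFactors = FALSE)
  }
  det <- as_detections(det)
  rownames(log) <- NULL
  list(detections = det, log = log)
}

# Substream index for a frame: parse the numeric suffix of ids like
# "frame_000017" so corruption of a frame does not depend on which other
# frames are in the batch; otherwise fall back to the batch position.
frame_index_of <- function(frame_id, fallback) {
  m <- regmatches(frame_id, regexpr("[0-9]+$", frame_id))
  if (length(m) == 1L && nzchar(m)) as.numeric(m) else fallback
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic detector contract
#'
#' Binds ground truth and an error model into a detector contract usable by
#' the k-fold harness and the monitoring pipeline: calling the returned
#' function with frame ids yields the corrupted detections for exactly
#' those frames, deterministically (per-frame substreams make the output
#' independent of batching).
#'
#' @param gt Ground-truth table.
#' @param em An [error_model()].
#' @param frame_width,frame_height Frame size override.
#' @return `function(frame_ids)` returning a detection table.
#' @export
synthetic_detector <- function(gt, em, frame_width = NULL,
                               frame_height = NULL) {
  gt <- as_annotations(gt)
  force(em)
  function(frame_ids) {
    corrupt(gt[gt$frame_id %in% frame_ids, , drop = FALSE], em,
            frames = frame_ids,
            frame_width = frame_width %||% attr(gt, "frame_width"),
            frame_height = frame_height %||% attr(gt, "frame_height")
    )$detections
  }
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard artifact dialects: one VOC XML per frame, a detection
#' CSV, a manifest CSV, and the truth log CSV.
#'
#' @param scenes Output of [generate_scenes()].
#' @param corrupted Output of [corrupt()].
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_synthetic_dataset <- function(scenes, corrupted, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_voc_dir(scenes$annotations, file.path(out_dir, "annotations"),
                frames = scenes$frames)
  det_path <- file.path(out_dir, "detections.csv")
  write_detections(corrupted$detections, det_path)
  man_path <- file.path(out_dir, "manifest.csv")
  write_manifest(scenes$manifest, man_path)
  log_path <- file.path(out_dir, "truth_log.csv")
  utils::write.csv(corrupted$log, log_path, row.names = FALSE)
  invisible(c(file.path(out_dir, "annotations"), det_path, man_path,
              log_path))
}
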