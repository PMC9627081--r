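# Confidence-threshold sweep and k-fold split/aggregation.
#
# The sweep deletes predictions whose confidence is lower than the threshold
# C_thr (strict <: survivors have confidence >= C_thr) and recomputes pooled
# precision/recall/F1 at each of the 101 grid points 0..100%. Because the
# greedy matcher processes detections in descending confidence order,
# deleting every detection below a threshold cannot change how the
# survivors were matched, so the whole sweep is derived from a single
# matching pass: TP(t) = matched detections with confidence >= t.

#' Confidence-threshold sweep
#'
#' Sweeps C_thr over 0..100% in 1% steps, recomputing pooled (micro-
#' averaged) precision, recall and F1 at each step, and selects the C_thr
#' maximizing F1, breaking ties toward the lowest threshold (which retains
#' the most recall).
#'
#' @param gt Ground-truth table.
#' @param det Detection table.
#' @param cfg An [eval_config()].
#' @param per_class Also return a per-class sweep? Default `FALSE` (the
#'   pooled sweep is what the operating threshold is selected on).
#' @return Object of class `jf_sweep`: list with `grid` (data frame `c_thr`,
#'   `TP`, `FP`, `FN`, `precision`, `recall`, `f1`), `selected` (one-row
#'   data frame at the F1-optimal C_thr), `degenerate` (`TRUE` when there
#'   were no detections), and optionally `per_class_grid`.
#' @export
threshold_sweep <- function(gt, det, cfg = eval_config(),
                            per_class = FALSE) {
  match <- classify_predictions(gt, det, cfg)
  grid <- sweep_from_match(match$detections$confidence,
                           match$detections$status == "TP",
                           sum(match$tallies$n_gt))
  sel <- which(grid$f1 == max(grid$f1))[1L]  # ties -> lowest c_thr
  out <- list(grid = grid, selected = grid[sel, , drop = FALSE],
              degenerate = nrow(det) == 0L)
  if (per_class) {
    out$per_class_grid <- do.call(rbind, lapply(
      as.character(match$catalog), function(cl) {
        rows <- match$detections$species == cl
        g <- sweep_from_match(match$detections$confidence[rows],
                              match$detections$status[rows] == "TP",
                              sum(match$tallies$n_gt[
                                match$tallies$class == cl]))
        g$class <- cl
        g
      }))
  }
  structure(out, class = "jf_sweep")
}

sweep_from_match <- function(confidence, is_tp, n_gt) {
  c_thr <- 0:100
  # survivor rule: delete confidence strictly below C_thr (percent scale)
  tp <- vapply(c_thr, function(t) {
    sum(is_tp & confidence * 100 >= t - 1e-9)
  }, 0L)
  fp <- vapply(c_thr, function(t) {
    sum(!is_tp & confidence * 100 >= t - 1e-9)
  }, 0L)
  fn <- n_gt - tp
  prf <- t(mapply(precision_recall_f1, tp, fp, fn))
  data.frame(c_thr = c_thr, TP = tp, FP = fp, FN = fn,
             precision = prf[, "precision"], recall = prf[, "recall"],
             f1 = prf[, "f1"])
}

#' @export
print.jf_sweep <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "Confidence-threshold sweep: C_thr = %d%% (P %.1f%%, R %.1f%%, F1 %.1f%%)\n",
    s$c_thr, s$precision, s$recall, s$f1))
  if (x$degenerate) cat("(degenerate: no detections)\n")
  invisible(x)
}

#' Split frames into k folds
#'
#' Reproducible partition of frame ids into k folds of as-equal-as-possible
#' size (sizes differ by at most 1). Splitting is at the frame level so all
#' instances of a frame stay together. With `strata`, frames are shuffled
#' within each stratum and dealt round-robin, balancing strata across folds
#' while keeping global fold sizes within 1.
#'
#' @param frames Character vector of unique frame ids.
#' @param k Number of folds, at least 2 and at most `length(frames)`.
#' @param seed Integer seed; the same seed always yields the same folds.
#' @param strata Optional per-frame labels (same length as `frames`), e.g.
#'   the dominant species of each frame, to stratify on.
#' @return Object of class `jf_folds`: list with `assignment` (data frame
#'   `frame_id`, `fold`), `k`, `seed`.
#' @export
make_folds <- function(frames, k = 5, seed = 1, strata = NULL) {
  frames <- as.character(frames)
  if (anyDuplicated(frames)) stop("make_folds: duplicate frame ids",
                                  call. = FALSE)
  n <- length(frames)
  if (k < 2 || k > n) {
    stop("make_folds: need 2 <= k <= number of frames (k=", k, ", n=", n,
         ")", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(strata)) {
    ord <- sample.int(n)
  } else {
    if (length(strata) != n) {
      stop("make_folds: strata must match frames in length", call. = FALSE)
    }
    groups <- split(seq_len(n), as.character(strata))
    groups <- groups[sample(names(groups))]
    ord <- unlist(lapply(groups, function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
  }
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  structure(list(assignment = data.frame(frame_id = frames, fold = fold,
                                         stringsAsFactors = FALSE),
                 k = k, seed = seed),
            class = "jf_folds")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Frames of one fold
#'
#' @param folds A `jf_folds` object.
#' @param i Fold number in `1..k`.
#' @param role `"test"` (frames in fold `i`) or `"train"` (the rest).
#' @return Character vector of frame ids.
#' @export
fold_frames <- function(folds, i, role = c("test", "train")) {
  role <- match.arg(role)
  a <- folds$assignment
  if (role == "test") a$frame_id[a$fold == i] else a$frame_id[a$fold != i]
}

#' Build a per-fold region report
#'
#' Evaluates one test set: per-class AP and mAP from
#' [evaluate_detections()], plus the F1-optimal operating point from
#' [threshold_sweep()] (C_thr, recall, precision, F1).
#'
#' @param gt,det Ground truth and detections restricted to the fold's test
#'   frames.
#' @param cfg An [eval_config()].
#' @param region Optional region name carried through to the report.
#' @return List of class `jf_report` with `region`, `per_class` (class, AP),
#'   `mAP`, `c_thr`, `recall`, `precision`, `f1`.
#' @export
fold_report <- function(gt, det, cfg = eval_config(), region = NA) {
  ev <- evaluate_detections(gt, det, cfg)
  sw <- threshold_sweep(gt, det, cfg)
  structure(list(region = region,
                 per_class = ev$per_class[, c("class", "AP")],
                 mAP = ev$mAP,
                 c_thr = sw$selected$c_thr,
                 recall = sw$selected$recall,
                 precision = sw$selected$precision,
                 f1 = sw$selected$f1),
            class = "jf_report")
}

#' Aggregate per-fold reports
#'
#' Unweighted arithmetic mean of every metric across folds (AP per class,
#' mAP, C_thr, recall, precision, F1). A class absent from some folds' test
#' sets (undefined AP) is averaged over the folds where it is defined; the
#' number of contributing folds is recorded as `n_folds`.
#'
#' @param reports List of `jf_report` objects sharing one class catalog.
#' @return A `jf_report` with an extra `n_folds` column in `per_class`.
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) == 0L) stop("aggregate_folds: no reports",
                                  call. = FALSE)
  cls <- lapply(reports, function(r) sort(r$per_class$class))
  if (length(unique(vapply(cls, paste, "", collapse = "\r"))) != 1L) {
    stop("aggregate_folds: fold reports have mismatched class catalogs",
         call. = FALSE)
  }
  classes <- reports[[1L]]$per_class$class
  ap <- sapply(reports, function(r) {
    r$per_class$AP[match(classes, r$per_class$class)]
  })
  ap <- matrix(ap, nrow = length(classes))
  per_class <- data.frame(
    class = classes,
    AP = rowMeans(ap, na.rm = TRUE),
    n_folds = rowSums(!is.na(ap)),
    stringsAsFactors = FALSE
  )
  per_class$AP[per_class$n_folds == 0L] <- NA_real_
  msum <- function(field) mean(vapply(reports, `[[`, 0, field))
  structure(list(region = reports[[1L]]$region,
                 per_class = per_class,
                 mAP = msum("mAP"), c_thr = msum("c_thr"),
                 recall = msum("recall"), precision = msum("precision"),
                 f1 = msum("f1"), k = length(reports)),
            class = "jf_report")
}

#' @export
print.jf_report <- function(x, ...) {
  if (!is.na(x$region)) cat("Region:", x$region, "\n")
  df <- x$per_class
  df$AP <- round(df$AP, 1)
  print(df, row.names = FALSE)
  cat(sprintf("mAP %.1f%% | C_thr %.1f%% | REC %.1f%% | PREC %.1f%% | F1 %.1f%%\n",
              x$mAP, x$c_thr, x$recall, x$precision, x$f1))
  invisible(x)
}

#' k-fold evaluation harness
#'
#' Splits frames into k folds, runs the supplied detector on each fold's
#' test frames, evaluates, and averages the per-fold reports. No training
#' happens here: the harness calls whatever detector contract it is given
#' once per fold.
#'
#' @param gt Ground-truth table covering all frames.
#' @param detector A detector contract: `function(frame_ids)` returning a
#'   detection table for those frames (see [synthetic_detector()] and
#'   [replay_detector()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the split.
#' @param cfg An [eval_config()].
#' @param strata Optional per-frame strata (see [make_folds()]); default
#'   stratifies on each frame's dominant species.
#' @param frames Optional character vector of all frames to split
#'   (defaults to the annotated frames); include frames without ground
#'   truth so their false positives enter the fold metrics.
#' @param region Optional region name.
#' @return List with `folds` (the `jf_folds`), `reports` (per fold) and
#'   `aggregate` (their mean).
#' @export
kfold_evaluate <- function(gt, detector, k = 5, seed = 1,
                           cfg = eval_config(), strata = NULL,
                           frames = NULL, region = NA) {
  gt <- as_annotations(gt)
  if (is.null(frames)) frames <- sort(unique(gt$frame_id))
  frames <- as.character(frames)
  if (is.null(strata)) {
    strata <- vapply(frames, function(f) {
      sp <- gt$species[gt$frame_id == f]
      if (length(sp) == 0L) "(none)" else
        names(sort(table(sp), decreasing = TRUE))[1L]
    }, "")
  }
  folds <- make_folds(frames, k = k, seed = seed, strata = strata)
  cat_all <- class_catalog(sort(unique(gt$species)))
  reports <- lapply(seq_len(k), function(i) {
    test <- fold_frames(folds, i, "test")
    gt_i <- gt[gt$frame_id %in% test, , drop = FALSE]
    det_i <- detector(test)
    cfg_i <- eval_config(thr_iou = cfg$thr_iou, catalog = cat_all)
    fold_report(gt_i, det_i, cfg_i, region = region)
  })
  list(folds = folds, reports = reports,
       aggregate = aggregate_folds(reports))
}

#' Replay detector
#'
#' Wraps a stored detection table as a detector contract: calling it with a
#' set of frame ids returns the stored detections for those frames. Used to
#' evaluate a detector's saved output through the k-fold harness.
#'
#' @param det Detection table.
#' @return `function(frame_ids)` returning the matching rows.
#' @export
replay_detector <- function(det) {
  det <- as_detections(det)
  function(frame_ids) det[det$frame_id %in% frame_ids, , drop = FALSE]
}
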