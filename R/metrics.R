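# VOC-protocol matching and detection metrics.
#
# A prediction is a true positive when its IoU with a same-frame, same-class
# ground-truth box meets the IoU threshold AND that ground-truth box has not
# already been claimed by a higher-confidence prediction; otherwise it is a
# false positive. Ground truth left unmatched is a false negative. Matching
# is greedy in descending confidence order with each ground-truth instance
# usable at most once, so duplicate hits on one instance count as FPs.

#' Evaluation configuration
#'
#' @param thr_iou IoU threshold for a localization match, strictly between 0
#'   and 1. A detection ties at exactly the threshold count as matching
#'   (`>=`). Default 0.5, the PASCAL VOC convention.
#' @param catalog Optional [class_catalog()]; when `NULL` it is derived from
#'   the union of ground-truth and detection labels at evaluation time.
#' @return List of class `jf_config`.
#' @export
eval_config <- function(thr_iou = 0.5, catalog = NULL) {
  if (!is.numeric(thr_iou) || length(thr_iou) != 1L ||
      thr_iou <= 0 || thr_iou >= 1) {
    stop("eval_config: thr_iou must lie strictly between 0 and 1",
         call. = FALSE)
  }
  structure(list(thr_iou = thr_iou, catalog = catalog),
            class = "jf_config")
}

resolve_catalog <- function(gt, det, cfg) {
  if (!is.null(cfg$catalog)) {
    check_labels(gt$species, cfg$catalog, "ground truth")
    check_labels(det$species, cfg$catalog, "detections")
    return(cfg$catalog)
  }
  class_catalog(sort(unique(c(gt$species, det$species))))
}

#' Match detections to ground truth
#'
#' Greedy confidence-ordered one-to-one assignment per frame and class (VOC
#' protocol). Confidence ties are broken by input order for determinism.
#'
#' @param gt Ground-truth table (see [as_annotations()]).
#' @param det Detection table (see [as_detections()]).
#' @param cfg An [eval_config()].
#' @return Object of class `jf_match`: a list with `detections` (the input
#'   rows plus `status` (`"TP"`/`"FP"`) and `matched_gt_id`), `gt` (input
#'   rows plus logical `matched`), `tallies` (per-class `TP`, `FP`, `FN`,
#'   `n_gt`), and the catalog.
#' @export
classify_predictions <- function(gt, det, cfg = eval_config()) {
  gt <- as_annotations(gt)
  det <- as_detections(det)
  catalog <- resolve_catalog(gt, det, cfg)

  status <- rep("FP", nrow(det))
  matched_gt_id <- rep(NA_character_, nrow(det))
  gt_matched <- rep(FALSE, nrow(gt))

  ord <- order(-det$confidence, seq_len(nrow(det)))
  for (d in ord) {
    cand <- which(!gt_matched &
                    gt$frame_id == det$frame_id[d] &
                    gt$species == det$species[d])
    if (length(cand) == 0L) next
    ious <- box_iou(det[d, , drop = FALSE], gt[cand, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= cfg$thr_iou) {
      status[d] <- "TP"
      matched_gt_id[d] <- gt$gt_id[cand[best]]
      gt_matched[cand[best]] <- TRUE
    }
  }

  tallies <- data.frame(class = as.character(catalog),
                        stringsAsFactors = FALSE)
  tallies$n_gt <- vapply(tallies$class,
                         function(cl) sum(gt$species == cl), 0L)
  tallies$TP <- vapply(tallies$class, function(cl) {
    sum(status == "TP" & det$species == cl)
  }, 0L)
  tallies$FP <- vapply(tallies$class, function(cl) {
    sum(status == "FP" & det$species == cl)
  }, 0L)
  tallies$FN <- tallies$n_gt - tallies$TP
  det$status <- status
  det$matched_gt_id <- matched_gt_id
  gt$matched <- gt_matched
  structure(list(detections = det, gt = gt, tallies = tallies,
                 catalog = catalog, thr_iou = cfg$thr_iou),
            class = "jf_match")
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), both as percentages;
#' F1 is their harmonic mean. Degenerate cases are defined as 0 (so that an
#' empty prediction set never looks optimal in a threshold sweep).
#'
#' @param tp,fp,fn Non-negative counts. Alternatively pass a `jf_match`
#'   object as `tp` and its pooled counts are used.
#' @return Named numeric vector `precision`, `recall`, `f1`, in percent.
#' @export
precision_recall_f1 <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "jf_match")) {
    t <- tp$tallies
    fp <- sum(t$FP); fn <- sum(t$FN); tp <- sum(t$TP)
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

# Area under the running-maximum precision envelope over recall, from a
# confidence-ranked TP/FP outcome vector (all-point interpolation).
ap_envelope <- function(is_tp, n_gt) {
  if (n_gt <= 0L) return(NA_real_)
  if (length(is_tp) == 0L) return(0)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  # running max from the right: envelope precision at each recall level
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Per-class average precision
#'
#' AP is the area under the maximum-precision envelope of the
#' precision-recall curve built by ranking the class's detections by
#' descending confidence (all-point interpolation). The recall denominator
#' is the total ground truth of the class. AP depends on confidences only
#' through their ranks. Classes without ground truth have undefined AP,
#' returned as `NA` (absent, not 0).
#'
#' @param match A `jf_match` from [classify_predictions()], or pass `gt`,
#'   `det`, `cfg` via `...` to match first.
#' @param class Class label; default all catalog classes.
#' @return Data frame `class`, `n_gt`, `TP`, `FP`, `FN`, `AP` (percent; `NA`
#'   when the class has no ground truth).
#' @export
average_precision <- function(match, class = NULL) {
  stopifnot(inherits(match, "jf_match"))
  classes <- if (is.null(class)) as.character(match$catalog) else class
  det <- match$detections
  out <- match$tallies[match(classes, match$tallies$class), , drop = FALSE]
  out$AP <- vapply(classes, function(cl) {
    rows <- which(det$species == cl)
    rows <- rows[order(-det$confidence[rows], rows)]
    ap <- ap_envelope(det$status[rows] == "TP",
                      sum(match$gt$species == cl))
    if (is.na(ap)) NA_real_ else 100 * ap
  }, 0)
  rownames(out) <- NULL
  out
}

#' Mean average precision
#'
#' Unweighted arithmetic mean of per-class AP values. Classes with undefined
#' AP (no ground truth) are excluded rather than counted as zero.
#'
#' @param aps Numeric vector of per-class APs in percent, or the data frame
#'   returned by [average_precision()].
#' @return mAP in percent.
#' @export
mean_ap <- function(aps) {
  if (is.data.frame(aps)) aps <- aps$AP
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0L) {
    stop("mean_ap: no class with a defined AP", call. = FALSE)
  }
  mean(aps)
}

#' Full evaluation report
#'
#' Runs [classify_predictions()], per-class [average_precision()] and
#' [mean_ap()] in one call.
#'
#' @param gt Ground-truth table.
#' @param det Detection table.
#' @param cfg An [eval_config()].
#' @return Object of class `jf_eval`: list with `per_class` (tallies + AP),
#'   `mAP`, `match`, and the config.
#' @export
evaluate_detections <- function(gt, det, cfg = eval_config()) {
  match <- classify_predictions(gt, det, cfg)
  per_class <- average_precision(match)
  structure(list(per_class = per_class, mAP = mean_ap(per_class),
                 match = match, thr_iou = cfg$thr_iou),
            class = "jf_eval")
}

#' @export
print.jf_eval <- function(x, ...) {
  cat("Detection evaluation (IoU threshold ", x$thr_iou, ")\n", sep = "")
  df <- x$per_class
  df$AP <- round(df$AP, 1)
  print(df, row.names = FALSE)
  cat(sprintf("mAP: %.1f%%\n", x$mAP))
  invisible(x)
}

#' Multiclass confusion matrix
#'
#' Each detection that overlaps ground truth (max-IoU instance, IoU at or
#' above the threshold) is assigned to the row of that instance's true
#' species, in the column of the detection's predicted species; rows are
#' normalized to percentages of their assigned detections. Detections with
#' no qualifying ground-truth overlap are background false positives: they
#' describe no true species, so they are excluded from the rows and
#' reported in a side tally per predicted species.
#'
#' @param gt Ground-truth table.
#' @param det Detection table.
#' @param cfg An [eval_config()].
#' @param conf_floor Optional minimum confidence (fraction); detections
#'   below it are ignored. Default `NULL` uses all detections.
#' @return Object of class `jf_confusion`: list with `percent` (N x N
#'   row-normalized matrix; rows with no assigned detections are `NA`),
#'   `counts`, `background_fp` (named counts per predicted species), and
#'   `catalog`.
#' @export
confusion_matrix <- function(gt, det, cfg = eval_config(),
                             conf_floor = NULL) {
  gt <- as_annotations(gt)
  det <- as_detections(det)
  catalog <- resolve_catalog(gt, det, cfg)
  if (!is.null(conf_floor)) {
    det <- det[det$confidence >= conf_floor, , drop = FALSE]
  }
  n <- length(catalog)
  counts <- matrix(0L, n, n, dimnames = list(true = as.character(catalog),
                                             assigned = as.character(catalog)))
  background <- stats::setNames(integer(n), as.character(catalog))
  for (d in seq_len(nrow(det))) {
    cand <- which(gt$frame_id == det$frame_id[d])
    row_cl <- NULL
    if (length(cand) > 0L) {
      ious <- box_iou(det[d, , drop = FALSE], gt[cand, , drop = FALSE])
      best <- which.max(ious)
      if (ious[best] >= cfg$thr_iou) row_cl <- gt$species[cand[best]]
    }
    if (is.null(row_cl)) {
      background[det$species[d]] <- background[det$species[d]] + 1L
    } else {
      counts[row_cl, det$species[d]] <- counts[row_cl, det$species[d]] + 1L
    }
  }
  totals <- rowSums(counts)
  percent <- counts * NA_real_
  nz <- totals > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / totals[nz]
  structure(list(percent = percent, counts = counts,
                 background_fp = background, catalog = catalog),
            class = "jf_confusion")
}

#' @export
print.jf_confusion <- function(x, digits = 1, ...) {
  cat("Multiclass confusion matrix (row %, true species x assigned)\n")
  print(round(x$percent, digits))
  if (sum(x$background_fp) > 0) {
    cat("Background FPs:", sum(x$background_fp), "\n")
  }
  invisible(x)
}

#' Write an evaluation report to JSON and the confusion matrix to CSV
#'
#' @param eval A `jf_eval` object.
#' @param cm Optional `jf_confusion` object.
#' @param json_path Output path for the JSON report.
#' @param cm_path Optional output path for the confusion-matrix CSV
#'   (labeled rows and columns, catalog order).
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(eval, json_path, cm = NULL, cm_path = NULL) {
  report <- list(
    config = list(thr_iou = eval$thr_iou),
    per_class = eval$per_class,
    mAP = eval$mAP
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(cm) && !is.null(cm_path)) {
    utils::write.csv(as.data.frame(round(cm$percent, 4)), cm_path)
  }
  invisible(json_path)
}
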