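# Axis-aligned box geometry. Internal convention everywhere in this package:
# 0-based, half-open pixel boxes [xmin, xmax) x [ymin, ymax), so that
# area = (xmax - xmin) * (ymax - ymin) and two boxes sharing only an edge are
# disjoint. Conversion to the 1-based inclusive VOC convention happens only
# at XML I/O (see read_voc_xml / write_voc_xml).

#' Validate bounding-box columns
#'
#' Checks that a data frame carries the four box columns and that every box
#' has strictly positive area. Degenerate (zero or negative area) boxes are
#' rejected here, at construction time, not inside geometry functions.
#'
#' @param df A data frame with numeric columns `xmin`, `ymin`, `xmax`, `ymax`
#'   in the internal 0-based half-open convention.
#' @param where Label used in error messages.
#' @return `df`, invisibly, if valid.
#' @export
validate_boxes <- function(df, where = "boxes") {
  needed <- c("xmin", "ymin", "xmax", "ymax")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop(where, ": column '", col, "' must be numeric and non-missing",
           call. = FALSE)
    }
  }
  bad <- which(df$xmax <= df$xmin | df$ymax <= df$ymin)
  if (length(bad) > 0L) {
    stop(where, ": degenerate box (non-positive area) at row ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Box areas
#'
#' @param boxes Data frame with `xmin`, `ymin`, `xmax`, `ymax` columns.
#' @return Numeric vector of areas in square pixels.
#' @export
box_area <- function(boxes) {
  (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)
}

#' Intersection over union of paired boxes
#'
#' Computes IoU elementwise between two sets of boxes of equal length (either
#' may also have a single row, which is recycled). IoU is the intersection
#' area divided by the union area; it is symmetric, equals 1 for identical
#' boxes and 0 for disjoint ones (boxes that share only an edge are disjoint
#' under the half-open convention).
#'
#' @param a,b Data frames of boxes (see [validate_boxes()]).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
#' @examples
#' a <- data.frame(xmin = 0, ymin = 0, xmax = 2, ymax = 2)
#' b <- data.frame(xmin = 1, ymin = 1, xmax = 3, ymax = 3)
#' box_iou(a, b)  # 1/7
box_iou <- function(a, b) {
  validate_boxes(a, "box_iou(a)")
  validate_boxes(b, "box_iou(b)")
  iw <- pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin)
  ih <- pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Pairwise IoU matrix
#'
#' @param a,b Data frames of boxes.
#' @return `nrow(a)` by `nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a, "iou_matrix(a)")
  validate_boxes(b, "iou_matrix(b)")
  iw <- pmax(outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax), 0)
  ih <- pmax(outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax), 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

# Greedy suppression on one group of boxes, assumed to belong to one frame
# (and one class when suppression is class-aware). Returns the row indices
# retained, in descending confidence order. Ties in confidence are broken by
# larger area, then by original input order, for determinism.
nms_group <- function(boxes, confidence, overlap_thr) {
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(-confidence, -box_area(boxes), seq_len(n))
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (length(ord) > 1L) {
      iou <- box_iou(boxes[i, , drop = FALSE], boxes)
      alive <- alive & (iou < overlap_thr)
    }
    alive[i] <- FALSE
  }
  keep
}

#' Non-maxima suppression
#'
#' Greedy NMS in descending confidence order: the highest-confidence box is
#' retained and every remaining box with IoU at or above `overlap_thr`
#' against it is suppressed; the procedure repeats on the survivors. By
#' default suppression is applied per frame and per class, so overlapping
#' detections of different species are never deleted; set
#' `per_class = FALSE` for class-agnostic suppression.
#'
#' @param detections Data frame with box columns, a `confidence` column in
#'   `[0, 1]`, and optionally `frame_id` and `species` columns used for
#'   grouping.
#' @param overlap_thr IoU threshold at or above which a lower-confidence box
#'   is suppressed. Default 0.5.
#' @param per_class Suppress only within a species? Default `TRUE`.
#' @return The retained rows, ordered by descending confidence (ties: larger
#'   area, then input order).
#' @export
nms <- function(detections, overlap_thr = 0.5, per_class = TRUE) {
  if (nrow(detections) == 0L) return(detections)
  validate_boxes(detections, "nms")
  if (!"confidence" %in% names(detections)) {
    stop("nms: detections need a 'confidence' column", call. = FALSE)
  }
  if (any(detections$confidence < 0 | detections$confidence > 1)) {
    stop("nms: confidences must lie in [0, 1]", call. = FALSE)
  }
  key <- rep("", nrow(detections))
  if ("frame_id" %in% names(detections)) {
    key <- paste0(key, detections$frame_id, "\r")
  }
  if (per_class && "species" %in% names(detections)) {
    key <- paste0(key, detections$species)
  }
  keep <- unlist(lapply(split(seq_len(nrow(detections)), key), function(idx) {
    idx[nms_group(detections[idx, , drop = FALSE],
                  detections$confidence[idx], overlap_thr)]
  }), use.names = FALSE)
  out <- detections[keep, , drop = FALSE]
  out <- out[order(-out$confidence, -box_area(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
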