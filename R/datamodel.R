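# Ground-truth and detection data model. Annotations and detections are
# plain data frames with documented columns; validators normalise and check
# them once at the boundary so downstream code can assume well-formed input.
#
#   annotations: frame_id, species, xmin, ymin, xmax, ymax  (+ optional gt_id)
#   detections:  frame_id, species, confidence, xmin, ymin, xmax, ymax
#   manifest:    video_id, frame_id, timestamp_s

#' Species class catalog
#'
#' An ordered set of species labels; its length is the dimension N of the
#' multiclass confusion matrix. Labels must be unique and non-empty.
#'
#' @param labels Character vector of species labels.
#' @return Character vector of class `jf_catalog`.
#' @export
class_catalog <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L || anyNA(labels) || any(!nzchar(labels))) {
    stop("class_catalog: labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("class_catalog: duplicate label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  structure(labels, class = c("jf_catalog", "character"))
}

#' Validate an annotation table
#'
#' @param df Data frame with `frame_id`, `species` and box columns.
#' @param catalog Optional [class_catalog()]; when given, every species must
#'   belong to it.
#' @return The validated data frame (with `frame_id`/`species` as character
#'   and a `gt_id` column added when absent).
#' @export
as_annotations <- function(df, catalog = NULL) {
  for (col in c("frame_id", "species")) {
    if (!col %in% names(df)) {
      stop("annotations: missing column '", col, "'", call. = FALSE)
    }
  }
  df$frame_id <- as.character(df$frame_id)
  df$species <- as.character(df$species)
  validate_boxes(df, "annotations")
  if (!is.null(catalog)) check_labels(df$species, catalog, "annotations")
  if (!"gt_id" %in% names(df)) {
    df$gt_id <- sprintf("g%06d", seq_len(nrow(df)))
  }
  rownames(df) <- NULL
  df
}

#' Validate a detection table
#'
#' Confidences are stored internally as fractions in `[0, 1]`; percentage
#' input is converted at this boundary.
#'
#' @param df Data frame with `frame_id`, `species`, `confidence` and box
#'   columns.
#' @param catalog Optional [class_catalog()].
#' @param confidence_unit `"fraction"` (default) or `"percent"`.
#' @return The validated data frame with fractional confidences.
#' @export
as_detections <- function(df, catalog = NULL,
                          confidence_unit = c("fraction", "percent")) {
  confidence_unit <- match.arg(confidence_unit)
  for (col in c("frame_id", "species", "confidence")) {
    if (!col %in% names(df)) {
      stop("detections: missing column '", col, "'", call. = FALSE)
    }
  }
  df$frame_id <- as.character(df$frame_id)
  df$species <- as.character(df$species)
  if (!is.numeric(df$confidence) || anyNA(df$confidence)) {
    stop("detections: confidence must be numeric and non-missing",
         call. = FALSE)
  }
  if (confidence_unit == "percent") df$confidence <- df$confidence / 100
  bad <- which(df$confidence < 0 | df$confidence > 1)
  if (length(bad) > 0L) {
    stop("detections: confidence outside [0, 1] at row ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  validate_boxes(df, "detections")
  if (!is.null(catalog)) check_labels(df$species, catalog, "detections")
  rownames(df) <- NULL
  df
}

check_labels <- function(species, catalog, where) {
  unknown <- setdiff(unique(species), catalog)
  if (length(unknown) > 0L) {
    stop(where, ": label(s) outside catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a frame manifest
#'
#' A manifest maps each frame of a video to its timestamp in seconds; in a
#' fixed-stride extraction (the default for the synthetic generator is one
#' frame every 5 s) timestamps advance by the stride. Timestamps must be
#' non-negative and strictly increasing within each video.
#'
#' @param df Data frame with `video_id`, `frame_id`, `timestamp_s`.
#' @return The validated manifest.
#' @export
as_manifest <- function(df) {
  for (col in c("video_id", "frame_id", "timestamp_s")) {
    if (!col %in% names(df)) {
      stop("manifest: missing column '", col, "'", call. = FALSE)
    }
  }
  df$video_id <- as.character(df$video_id)
  df$frame_id <- as.character(df$frame_id)
  if (!is.numeric(df$timestamp_s) || anyNA(df$timestamp_s) ||
      any(df$timestamp_s < 0)) {
    stop("manifest: timestamps must be non-negative numbers", call. = FALSE)
  }
  if (anyDuplicated(df$frame_id)) {
    stop("manifest: duplicate frame_id(s)", call. = FALSE)
  }
  for (vid in unique(df$video_id)) {
    ts <- df$timestamp_s[df$video_id == vid]
    if (any(diff(ts) <= 0)) {
      stop("manifest: timestamps not strictly increasing for video '",
           vid, "'", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Cross-check frame ids between a data set and a manifest
#'
#' @param frames Character vector of frame ids, or a data frame with a
#'   `frame_id` column (annotations or detections).
#' @param manifest A manifest (see [as_manifest()]).
#' @return List with `missing_from_manifest` (frames present in the data but
#'   absent from the manifest) and `missing_from_data` (the converse), plus
#'   logical `ok`.
#' @export
validate_against_manifest <- function(frames, manifest) {
  if (is.data.frame(frames)) frames <- frames$frame_id
  frames <- unique(as.character(frames))
  manifest <- as_manifest(manifest)
  out <- list(
    missing_from_manifest = setdiff(frames, manifest$frame_id),
    missing_from_data = setdiff(manifest$frame_id, frames)
  )
  out$ok <- length(out$missing_from_manifest) == 0L
  out
}
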