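# Flat-file I/O for detection tables and frame manifests.
# Detection CSV header: frame_id,species,confidence,xmin,ymin,xmax,ymax
# JSON-lines: one object per line with the same fields.
# Manifest CSV header: video_id,frame_id,timestamp_s

#' Read a detection file (CSV or JSON-lines)
#'
#' CSV files must carry the header `frame_id,species,confidence,xmin,ymin,
#' xmax,ymax`; files ending in `.jsonl`/`.ndjson` are read as one JSON
#' object per line with the same fields. Confidences may be stored as
#' fractions or percentages; declare which with `confidence_unit`.
#' Validation failures report the offending line number.
#'
#' @param path Input path.
#' @param confidence_unit `"fraction"` (default) or `"percent"`.
#' @param catalog Optional [class_catalog()] to check labels against.
#' @return Validated detection data frame with fractional confidences.
#' @export
read_detections <- function(path, confidence_unit = c("fraction", "percent"),
                            catalog = NULL) {
  confidence_unit <- match.arg(confidence_unit)
  if (!file.exists(path)) {
    stop("read_detections: no such file '", path, "'", call. = FALSE)
  }
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
        stop("read_detections: '", path, "' line ", i, ": invalid JSON",
             call. = FALSE)
      })
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    first_data_line <- 1L
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    first_data_line <- 2L  # header occupies line 1
  }
  needed <- c("frame_id", "species", "confidence",
              "xmin", "ymin", "xmax", "ymax")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("read_detections: '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  line_of <- function(row) row + first_data_line - 1L
  for (col in c("confidence", "xmin", "ymin", "xmax", "ymax")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stop("read_detections: '", path, "' line ", line_of(bad[1]),
           ": non-numeric ", col, call. = FALSE)
    }
    df[[col]] <- vals
  }
  hi <- if (confidence_unit == "percent") 100 else 1
  bad <- which(df$confidence < 0 | df$confidence > hi)
  if (length(bad) > 0L) {
    stop("read_detections: '", path, "' line ", line_of(bad[1]),
         ": confidence ", df$confidence[bad[1]], " outside [0, ", hi, "]",
         call. = FALSE)
  }
  bad <- which(df$xmax <= df$xmin | df$ymax <= df$ymin)
  if (length(bad) > 0L) {
    stop("read_detections: '", path, "' line ", line_of(bad[1]),
         ": degenerate box", call. = FALSE)
  }
  as_detections(df, catalog = catalog, confidence_unit = confidence_unit)
}

#' Write a detection table to CSV
#'
#' @param detections Detection data frame (fractional confidences).
#' @param path Output path.
#' @param confidence_unit Unit to write: `"fraction"` (default) or
#'   `"percent"`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path,
                             confidence_unit = c("fraction", "percent")) {
  confidence_unit <- match.arg(confidence_unit)
  out <- detections[, c("frame_id", "species", "confidence",
                        "xmin", "ymin", "xmax", "ymax")]
  if (confidence_unit == "percent") out$confidence <- out$confidence * 100
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a frame manifest CSV
#'
#' @param path CSV with header `video_id,frame_id,timestamp_s`.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  as_manifest(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(video_id = "character",
                                             frame_id = "character")))
}

#' Write a frame manifest CSV
#'
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as_manifest(manifest)[, c("video_id", "frame_id",
                                             "timestamp_s")],
                   path, row.names = FALSE)
  invisible(path)
}
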