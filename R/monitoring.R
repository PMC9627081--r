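# Deployment-side monitoring pipeline: pluggable detector -> per-class NMS
# -> confidence-threshold filter -> timestamped per-detection log ->
# abundance and diversity time series. Real-time operation is modeled as a
# batch pass over a frame manifest; records are per-detection (no tracking
# of individuals across frames).

#' Run the detection pipeline over a frame manifest
#'
#' For each frame: run the detector, suppress duplicates with per-class
#' NMS, delete detections whose confidence is lower than the operating
#' threshold `c_thr` (survivors have confidence at or above it), and emit
#' one timestamped monitoring record per surviving detection.
#'
#' @param frames Character vector of frame ids to process.
#' @param detector Detector contract: `function(frame_ids)` returning a
#'   detection table.
#' @param manifest Frame manifest covering every requested frame (frames
#'   missing from it are an error, listed in the message).
#' @param nms_thr NMS overlap threshold (default 0.5).
#' @param c_thr Operating confidence threshold in percent (default 0:
#'   keep everything).
#' @param confusion Optional `jf_confusion` (or percent matrix) from a
#'   prior evaluation; when given, each record carries the confusion
#'   indicator of its predicted species (see
#'   [attach_confusion_indicator()]).
#' @return Data frame of monitoring records: `timestamp_s`, `video_id`,
#'   `frame_id`, `species`, `confidence_pct`, `confusion_indicator_pct`
#'   (NA when no confusion matrix was supplied), plus the box columns.
#' @export
run_detection_pipeline <- function(frames, detector, manifest,
                                   nms_thr = 0.5, c_thr = 0,
                                   confusion = NULL) {
  manifest <- as_manifest(manifest)
  frames <- as.character(frames)
  orphans <- setdiff(frames, manifest$frame_id)
  if (length(orphans) > 0L) {
    stop("run_detection_pipeline: frame(s) missing from manifest: ",
         paste(utils::head(orphans, 10L), collapse = ", "), call. = FALSE)
  }
  det <- as_detections(detector(frames))
  det <- nms(det, overlap_thr = nms_thr, per_class = TRUE)
  det <- det[det$confidence * 100 >= c_thr - 1e-9, , drop = FALSE]
  idx <- match(det$frame_id, manifest$frame_id)
  rec <- data.frame(
    timestamp_s = manifest$timestamp_s[idx],
    video_id = manifest$video_id[idx],
    frame_id = det$frame_id,
    species = det$species,
    confidence_pct = det$confidence * 100,
    confusion_indicator_pct = NA_real_,
    xmin = det$xmin, ymin = det$ymin, xmax = det$xmax, ymax = det$ymax,
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$timestamp_s, rec$frame_id, -rec$confidence_pct), ,
             drop = FALSE]
  rownames(rec) <- NULL
  if (!is.null(confusion)) {
    rec <- attach_confusion_indicator(rec, confusion)
  }
  rec
}

#' Attach the confusion indicator to monitoring records
#'
#' The confusion indicator of a record is 100 minus the diagonal entry of
#' its predicted species' row in a previously evaluated confusion matrix,
#' i.e. the evaluated misassignment rate of that species, in percent.
#'
#' @param records Monitoring records (see [run_detection_pipeline()]).
#' @param confusion A `jf_confusion`, or a row-normalized percent matrix
#'   with species as row/column names.
#' @return `records` with `confusion_indicator_pct` filled. A record whose
#'   species is absent from the matrix is an error.
#' @export
attach_confusion_indicator <- function(records, confusion) {
  pm <- if (inherits(confusion, "jf_confusion")) confusion$percent else
    confusion
  unknown <- setdiff(unique(records$species), rownames(pm))
  if (length(unknown) > 0L) {
    stop("attach_confusion_indicator: species absent from confusion ",
         "matrix: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  diag_pct <- diag(pm)[records$species]
  records$confusion_indicator_pct <- 100 - unname(diag_pct)
  records
}

#' Read a stored confusion matrix CSV
#'
#' Reads a row-normalized percent confusion matrix with species row and
#' column labels (first CSV column = row labels); `-` or empty cells are
#' zero.
#'
#' @param path CSV path.
#' @return Numeric percent matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- apply(m, 2L, function(col) {
    col <- trimws(as.character(col))
    col[col %in% c("-", "‐", "‑", "–", "")] <- "0"
    suppressWarnings(as.numeric(sub("%$", "", col)))
  })
  if (anyNA(m)) stop("read_confusion_csv: non-numeric cell in '", path,
                     "'", call. = FALSE)
  rownames(m) <- rn
  m
}

#' Abundance and diversity time series
#'
#' Bins monitoring records into half-open intervals `[t, t + interval_s)`
#' tiling the observed time range (starting at the interval boundary at or
#' below the earliest record). For each interval: per-species counts,
#' species richness (number of species with a positive count) and Shannon
#' diversity H = -sum p log p (natural log) over within-interval species
#' proportions.
#'
#' @param records Monitoring records.
#' @param interval_s Interval length in seconds (> 0).
#' @return Object of class `jf_abundance`: list with `counts` (long data
#'   frame `interval_start_s`, `species`, `count`), `summary`
#'   (`interval_start_s`, `total`, `richness`, `shannon`), and
#'   `interval_s`. Empty input yields zero intervals.
#' @export
abundance_series <- function(records, interval_s) {
  if (!is.numeric(interval_s) || interval_s <= 0) {
    stop("abundance_series: interval_s must be positive", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(structure(list(
      counts = data.frame(interval_start_s = numeric(0),
                          species = character(0), count = integer(0)),
      summary = data.frame(interval_start_s = numeric(0),
                           total = integer(0), richness = integer(0),
                           shannon = numeric(0)),
      interval_s = interval_s), class = "jf_abundance"))
  }
  start0 <- floor(min(records$timestamp_s) / interval_s) * interval_s
  starts <- seq(start0,
                floor(max(records$timestamp_s) / interval_s) * interval_s,
                by = interval_s)
  bin <- floor((records$timestamp_s - start0) / interval_s)
  species <- sort(unique(records$species))
  tab <- table(factor(bin, levels = seq_along(starts) - 1L),
               factor(records$species, levels = species))
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("bin", "species", "count")
  counts$interval_start_s <- starts[as.integer(counts$bin) + 1L]
  counts <- counts[order(counts$interval_start_s, counts$species),
                   c("interval_start_s", "species", "count")]
  rownames(counts) <- NULL
  summ <- do.call(rbind, lapply(seq_along(starts), function(i) {
    n <- as.integer(tab[i, ])
    tot <- sum(n)
    p <- n[n > 0] / tot
    data.frame(interval_start_s = starts[i], total = tot,
               richness = sum(n > 0),
               shannon = if (tot > 0) -sum(p * log(p)) else 0)
  }))
  structure(list(counts = counts, summary = summ, interval_s = interval_s),
            class = "jf_abundance")
}

#' @export
print.jf_abundance <- function(x, ...) {
  cat(sprintf("Abundance series: %d interval(s) of %gs, %d record(s)\n",
              nrow(x$summary), x$interval_s, sum(x$counts$count)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write monitoring and abundance outputs
#'
#' @param records Monitoring records.
#' @param series A `jf_abundance` (optional).
#' @param out_dir Output directory.
#' @return Invisibly, written paths.
#' @export
write_monitoring <- function(records, series = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mon <- file.path(out_dir, "monitoring.csv")
  utils::write.csv(records[, c("timestamp_s", "video_id", "frame_id",
                               "species", "confidence_pct",
                               "confusion_indicator_pct")],
                   mon, row.names = FALSE)
  paths <- mon
  if (!is.null(series)) {
    ab <- file.path(out_dir, "abundance.csv")
    utils::write.csv(series$counts, ab, row.names = FALSE)
    su <- file.path(out_dir, "abundance_summary.csv")
    utils::write.csv(series$summary, su, row.names = FALSE)
    paths <- c(paths, ab, su)
  }
  invisible(paths)
}
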