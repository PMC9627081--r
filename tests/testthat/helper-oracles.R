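# Independent oracles and fixture builders. These deliberately use the
# slowest most literal formulation of each quantity (pixel counting,
# rectangle sums, per-step re-matching) so they share no code path with
# the implementation they check.

# IoU by counting unit pixel cells covered by each integer box.
pixel_iou_oracle <- function(a, b) {
  cells <- function(bx) {
    xs <- seq(bx$xmin, bx$xmax - 1)
    ys <- seq(bx$ymin, bx$ymax - 1)
    paste(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# AP as an explicit rectangle sum over the distinct recall levels: for each
# achieved recall level r_j, the rectangle (r_{j-1}, r_j] gets the maximum
# precision attained at any rank whose recall is >= r_j.
ap_rectangle_oracle <- function(is_tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(is_tp) == 0) return(0)
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  levels <- sort(unique(rec[rec > 0]))
  total <- 0
  prev <- 0
  for (r in levels) {
    total <- total + (r - prev) * max(prec[rec >= r])
    prev <- r
  }
  total
}

# One-row box helper.
bx <- function(xmin, ymin, xmax, ymax) {
  data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}

# Small hand-built ground truth / detection tables.
gt_row <- function(frame, species, xmin, ymin, xmax, ymax) {
  data.frame(frame_id = frame, species = species, xmin = xmin, ymin = ymin,
             xmax = xmax, ymax = ymax, stringsAsFactors = FALSE)
}

det_row <- function(frame, species, conf, xmin, ymin, xmax, ymax) {
  data.frame(frame_id = frame, species = species, confidence = conf,
             xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
             stringsAsFactors = FALSE)
}

# Random integer boxes inside a grid, guaranteed non-degenerate.
random_boxes <- function(n, lim = 50) {
  x1 <- sample.int(lim - 1, n, replace = TRUE) - 1
  y1 <- sample.int(lim - 1, n, replace = TRUE) - 1
  w <- sample.int(lim, n, replace = TRUE)
  h <- sample.int(lim, n, replace = TRUE)
  data.frame(xmin = x1, ymin = y1,
             xmax = pmin(x1 + w, lim), ymax = pmin(y1 + h, lim))
}

# Random annotation set over a few frames/species for round-trip tests.
random_annotations <- function(n_frames = 4, max_per_frame = 5,
                               species = c("Aurelia aurita",
                                           "Pelagia noctiluca",
                                           "Rhizostoma pulmo")) {
  rows <- lapply(seq_len(n_frames), function(i) {
    n <- sample.int(max_per_frame + 1, 1) - 1
    if (n == 0) return(NULL)
    b <- random_boxes(n, lim = 200)
    data.frame(frame_id = sprintf("frame_%03d", i),
               species = sample(species, n, replace = TRUE),
               b, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- gt_row("frame_001", species[1], 0, 0, 10, 10)
  }
  out
}

# Naive threshold sweep: filter and re-match from scratch at every step.
naive_sweep_oracle <- function(gt, det, cfg = eval_config()) {
  do.call(rbind, lapply(0:100, function(t) {
    kept <- det[det$confidence * 100 >= t - 1e-9, , drop = FALSE]
    m <- classify_predictions(gt, kept, cfg)
    prf <- precision_recall_f1(m)
    data.frame(c_thr = t, precision = unname(prf["precision"]),
               recall = unname(prf["recall"]), f1 = unname(prf["f1"]))
  }))
}
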