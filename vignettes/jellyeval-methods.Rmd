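---
title: "Methods: evaluating detectors for camera-based jellyfish monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating detectors for camera-based jellyfish monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyeval)
```

# The problem

A detector-based monitoring system for jellyfish consists of a trained
object detector plus a scaffold of deterministic computation: matching
predictions to annotations, scoring, choosing an operating threshold,
deciding which species each regional deployment should distinguish, and
aggregating detections into ecological time series. jellyeval implements
that scaffold. The detector itself is a *contract* — any function mapping
frame ids to `(box, species, confidence)` rows — so the scaffold can be
exercised and validated with a synthetic detector whose error structure is
known exactly.

# Matching model and metrics

**Geometry.** Boxes are axis-aligned, stored 0-based and half-open
(`[xmin, xmax) × [ymin, ymax)`), which makes area and intersection
arithmetic exact in integers and makes "share only an edge" mean disjoint.
The LabelImg VOC XML dialect is 1-based inclusive; conversion happens only
at XML I/O. Degenerate (zero-area) boxes are rejected at construction, so
geometry functions never see them.

**Matching.** A prediction is a true positive when its IoU with a
same-frame, same-class ground-truth box is at least `thr_iou` and that box
is still unclaimed; matching is greedy in descending confidence with each
ground-truth instance usable once, so duplicate hits are false positives.
Ties at exactly the threshold count as matching (`>=`). Confidence ties are
broken by input order for determinism. `thr_iou` defaults to 0.5, the
PASCAL VOC convention for this class of evaluation.

**AP.** Per class, detections are ranked by descending confidence and AP is
the area under the running-maximum precision envelope over recall
(all-point interpolation, not the older 11-point variant), with the
recall denominator equal to the class's total ground truth. AP therefore
depends on confidences only through ranks — a property tested explicitly.
A class with no ground truth has *undefined* AP, reported as `NA` and
excluded from mAP rather than counted as zero; a class with ground truth
and no detections has AP 0. mAP is the unweighted mean.

**Degenerate-count conventions.** With no predictions, precision is
defined as 0 (not 100 or undefined) and likewise recall with no ground
truth; F1 is 0 whenever precision + recall is 0. The asymmetric-looking
choice for precision is deliberate: in the threshold sweep it prevents
"predict nothing" from scoring as a perfect operating point.

**Confusion matrix.** Each detection overlapping ground truth (max-IoU
instance at `thr_iou` or better, without the one-to-one constraint) is
assigned to its true species' row under its predicted species' column;
rows are normalized to percent. Detections with no qualifying overlap are
background false positives; they describe no true species, so they live in
a side tally instead of distorting the rows. By default the matrix uses
all detections; an optional confidence floor restricts it to the operating
regime, since either choice is defensible and reports should say which
was used.

# Threshold sweep and cross-validation

The sweep deletes predictions with confidence strictly below C_thr
(survivors have confidence ≥ C_thr) at each of the 101 grid points
0–100 % and recomputes pooled (micro-averaged) precision, recall and F1.
The implementation exploits an exact equivalence: greedy
confidence-ordered matching is unaffected by deleting lower-confidence
detections, so one matching pass yields the entire grid
(`TP(t)` = matched detections with confidence ≥ t). The test suite
verifies this against a naive oracle that re-filters and re-matches at
every step. F1 ties are broken toward the lowest C_thr, which retains the
most recall. At C_thr = 0 the sweep reproduces the unswept metrics.

Folds are built at the *frame* level — all instances of a frame stay
together — because consecutive frames of one video are near-duplicates and
instance-level splitting would leak. Sizes differ by at most one.
Stratification (on each frame's dominant species by default) is available
and on in the k-fold harness: it shuffles within strata and deals
round-robin, balancing species across folds while preserving the size
bound. Fold reports carry per-class AP, mAP, and the sweep's operating
point (C_thr, recall, precision, F1); aggregation is the unweighted mean
per metric, with classes absent from some folds averaged over the folds
where they are defined and their coverage recorded. No training happens in
the harness — it calls whatever detector contract it is given once per
fold.

# Regional sub-models

Basins are clustered on their species presence/absence vectors using plain
Euclidean distance. The wording "similarity matrix based on Euclidean
distances" in this literature is loose; converting a distance to a
similarity and back adds nothing, so the distance is used directly.
Grouping is made reproducible with average-linkage agglomerative
clustering cut at `k` (default 4) rather than reading clusters off an
ordination plot by eye; classical-MDS coordinates of the same distance
matrix are emitted so the visual procedure can be replicated too. Whether
other practitioners' linkage or ordination settings match these defaults
is not knowable from published descriptions; they are this package's
convention. Clustering is invariant to row and column order (tested as a
partition).

Each region's sub-model catalog is the species present in at least one
member basin. Filtering a dataset to a region never alters geometry, only
membership. A species present in no basin is unroutable and is an explicit
error at routing time rather than a silent empty result. The bundled
15-species table (collapsed to four region groups) yields catalogs of
12 / 7 / 4 / 4 species.

The design claim behind regionalization — separating allopatric lookalike
species into different catalogs removes their mutual confusion and raises
per-class AP — is reproduced as a property test: two species with a
planted 30–35 % mutual confusion but disjoint regional footage evaluate
strictly better per region than pooled, on the same corrupted detections.

# Monitoring pipeline

Deployment is modeled as a batch pass over a frame manifest:
detector → per-class NMS → delete confidence < C_thr → one record per
surviving detection, timestamped from the manifest. NMS is class-aware by
default so overlapping individuals of different species are never merged;
the overlap threshold (default 0.5) and class-awareness are configuration,
as no standard fixes them. NMS confidence ties are broken by larger box
area, then input order, for determinism.

Each record carries a confidence (percent) and a *confusion indicator*,
defined here as 100 minus the diagonal entry of the predicted species' row
in a previously evaluated confusion matrix — i.e. the species' evaluated
misassignment rate. That is the natural scalar available from the
evaluation stage; the matrix used should accompany the data file as
provenance.

Abundance series bin records into half-open intervals tiling the observed
time range. Per interval: per-species counts, richness, and Shannon
diversity `H = -sum(p log p)` with the natural log (richness is reported
alongside since "diversity" alone is ambiguous). Counts conserve records
exactly. Records are per-detection: the same individual seen in
consecutive frames counts each time. No tracking is attempted — a known
limitation shared with any per-frame detector log; abundances are
therefore relative indices, comparable across time under constant frame
rate and detection conditions, not censuses.

# Synthetic data: what it emulates and what it does not

`generate_scenes()` emulates fixed-stride frame extraction from video
(default one frame per 5 s) with per-frame, per-class Poisson instance
counts, uniform box sizes (default 40–160 px sides in a 1280×720 frame)
and uniform placement; a bloom mode places instances in overlapping
Gaussian clusters, mimicking the dense aggregations that bloom-forming
species such as *Aurelia aurita* produce and that make individuals hard
to separate. `corrupt()` plants, independently per instance: a per-class
miss probability, a label drawn from a row-stochastic confusion matrix,
Gaussian corner jitter scaled to box side, plus per-frame Poisson clutter.
Confidences are Beta-distributed — high (Beta(8, 2)) for correct labels,
low (Beta(2, 4)) for confused and clutter detections — because a sweep
only has structure to find when confidence carries signal; all of this is
configurable. Every emitted detection's hidden origin is logged, so tests
can compare measured rates against planted ones with exact binomial
confidence intervals.

Randomness uses a global seed with per-frame substreams, so generation and
corruption are reproducible regardless of how frames are batched — the
synthetic detector returns identical output whether called per frame or
per fold. Within a frame, draws are staged (misses, then jitter, then
labels, then confidences), so detection sets at nested miss rates are
nested and quality degrades monotonically along a rate grid.

What passing tests show: the matching, AP, sweep, confusion, routing and
aggregation machinery is correct against independent oracles and recovers
planted parameters within sampling error. What they do not show: anything
about a real detector's accuracy on real imagery. Real detection errors
are correlated across frames and with image conditions (turbidity,
lighting, body deformation), boxes of real annotators are noisy, and real
confidence distributions are not Beta; the synthetic model makes errors
independent by design so that its rates are identifiable.

# Numerical choices and problem sizes

- Internal confidences are fractions in [0, 1]; percentages appear only at
  I/O and reporting. Threshold comparisons against the percent grid use a
  1e-9 slack to absorb decimal-fraction rounding (e.g. 0.674 × 100 vs 67.4).
- Report display rounds to one decimal in percent; full precision is kept
  internally and in JSON outputs.
- The sweep's strict-< deletion rule means a hypothetical confidence of
  exactly 1.0 would survive C_thr = 100; Beta-distributed confidences are
  almost surely below 1, so in practice nothing survives the last grid
  point.
- Test and acceptance simulations use 600–800 frames at rate 2 (about
  2400–3200 instances) where binomial recovery of planted rates is
  checked, and 15–150 frames elsewhere; these sizes put the planted-rate
  confidence intervals at roughly ±1.5 % while keeping the whole suite
  fast on a single CPU.
- The CLI accepts flags only (percent units at the surface); programmatic
  configuration is the R functions themselves rather than a config-file
  layer.

# Known limitations

- AP is single-threshold (IoU 0.5); COCO-style averaged-IoU AP is out of
  scope, as are rotated boxes and pixel masks.
- The confusion matrix assigns by max-IoU overlap without exclusivity;
  under extreme crowding a detection straddling two instances contributes
  to the row of the better-overlapped one only.
- Whether historical studies swept C_thr before or after building their
  confusion matrices is typically unstated; the default here (no floor) is
  one documented choice, not the only one.
- Abundance does not deduplicate individuals across frames (no tracking).
- The video-level fold mode is expressible by passing video ids as strata
  or frames grouped by video, but leakage between visually similar videos
  of the same bloom cannot be ruled out by any split.
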