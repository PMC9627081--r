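Package: jellyeval
Title: Detection Evaluation and Regional Routing for Camera-Based
    Jellyfish Monitoring
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for evaluating object detectors used in camera-based
    jellyfish monitoring. Provides axis-aligned box geometry (intersection
    over union, per-class non-maxima suppression), readers and writers for
    LabelImg PASCAL-VOC XML annotations, detection tables and frame
    manifests, VOC-protocol greedy matching into true/false positives,
    precision/recall/F1, all-point interpolated average precision and mAP,
    multiclass confusion matrices, confidence-threshold sweeps that select
    the F1-optimal operating point, k-fold split and aggregation,
    biogeographic sub-model routing from species-by-basin presence/absence
    tables, a monitoring pipeline that turns detections into per-detection
    logs and abundance/diversity time series, and a synthetic scene and
    detector simulator with a known error structure so the whole stack is
    testable without a trained network.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
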