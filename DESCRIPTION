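Package: rrverify
Title: Biometric Verification from Beat-to-Beat Heartbeat Interval Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies whether two windows of beat-to-beat (RR) heartbeat
    intervals come from the same individual. Implements the full pipeline:
    simulation of mouse-like RR cohorts with per-subject dynamical
    signatures, aging drift, autonomic-blockade drug effects and
    out-of-range artifacts; range-based artifact filtering with linear
    interpolation and non-overlapping fixed-length windowing; balanced
    labelled pair construction under complete-dataset and partial-dataset
    protocols; a Siamese one-dimensional convolutional encoder trained
    with a cosine-similarity contrastive loss; and threshold-based
    evaluation with FAR/FRR curves, equal error rate, fold-wise
    coefficient of variation, and a TOST equivalence procedure for age
    robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    withr,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
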