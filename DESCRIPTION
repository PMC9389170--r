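Package: apneanet
Title: Sleep Apnea Detection from Single-Lead ECG with a Convolutional
    BiGRU Attention Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end detection of sleep apnea from single-lead
    electrocardiogram recordings. Detects R-peaks with a Hamilton-style
    adaptive-threshold detector, cleans RR-interval and R-amplitude series
    with median filtering, resamples five-minute context windows to
    fixed-length model inputs by cubic interpolation, and classifies each
    minute as apneic or normal with a stacked convolutional / bidirectional
    GRU network with dot-product attention, trained by mini-batch Adam on
    binary cross-entropy. Per-recording diagnosis is derived from the
    apnea-hypopnea index of the predicted minutes, with cohort-level mean
    absolute error and Pearson correlation. Includes readers for WFDB and
    EDF signal files and respiratory event tables, and a synthetic ECG
    generator with known beat times and planted apnea episodes so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
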