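Package: bcgsleep
Title: Sleep Apnea Severity Assessment from Ballistocardiogram Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing sleep apnea syndrome severity from
    single-channel ballistocardiogram (BCG) recordings. Implements the full
    chain from raw signal to an apnea-hypopnoea index (AHI) report: wavelet
    multiresolution smoothing, overlapped sliding-window heartbeat (trough)
    detection, rule-based RR-interval correction, cubic-spline tachogram
    resampling, physiologically constrained iterative cumulative-sum-of-squares
    (ICSS) variance change-point detection of sleep-related breathing events,
    heart-rate-variability feature extraction (time-domain, Burg
    autoregressive spectral, detrended fluctuation analysis, sample entropy),
    feature selection and nested cross-validated classification, and
    AHI-based severity staging. Includes seeded synthetic-signal generators
    so the whole pipeline can be exercised and validated without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
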