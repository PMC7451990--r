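Package: dynstok
Title: Self-Tuning Optimized Kalman Filtering for Time-Varying MVAR
    Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive estimation of time-varying multivariate
    autoregressive (tvMVAR) models from multi-trial neural time-series.
    Implements the Self-Tuning Optimized Kalman filter (STOK), an
    adaptive least-squares filter with damped-SVD regularization and a
    self-tuning memory decay, alongside the classical general linear
    Kalman filter with trace-approximated measurement noise. Provides
    frequency-resolved directed-connectivity measures (squared
    row-normalized partial directed coherence, parametric power
    spectral density), a regime-switching surrogate-network simulator
    with noise and spatial-mixing corruption operators, and an ROC/AUC
    validation harness for benchmarking network-tracking performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
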