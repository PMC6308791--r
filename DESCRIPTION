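Package: biokey
Title: Biometric Identification from Paired ECG and Blood-Oxygen Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for biometric human identification from wearable-sensor
    biosignals. Implements quantization sparse matrix identification (QSMI):
    paired ECG and blood-oxygen (SpO2) series are mapped into a 2-D counting
    matrix, quantized with a sliding mask into a small number of levels,
    stored in coordinate (COO) sparse form and matched by Pearson correlation.
    Also implements multi-dimensional identification (MDI): multi-lead ECG
    sessions are mapped into a reduced J-dimensional integer space, summarized
    as sparse element sequences and matched by multi-dimensional dynamic time
    warping. Four reference algorithms (reduced binary patterns, fiducial
    waveform features, a wavelet pipeline, and a sparse-Euclidean baseline
    with PCA) share a common enrollment/scoring contract, and an evaluation
    harness computes false-acceptance and false-rejection rates with
    threshold sweeping. A seeded synthetic biosignal cohort generator
    provides reproducible end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
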