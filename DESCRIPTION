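Package: physiowork
Title: Driver Mental Workload Classification from ECG, EDA and Respiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study binary mental-workload classification from
    multi-channel physiological recordings (ECG, electrodermal activity and
    respiration) acquired over a rest baseline followed by a task phase.
    Provides a synthetic cohort generator with full ground truth, signal
    preprocessing (zero-phase filtering, R-peak and breath-cycle detection,
    convex tonic/phasic electrodermal decomposition with skin-conductance
    response detection), a 61-indicator psychophysiological feature catalog
    spanning time-, frequency- and nonlinear-domain heart-rate variability,
    respiratory variability, electrodermal level/response statistics and
    respiratory sinus arrhythmia, baseline-delta feature engineering over
    configurable segmentation levels, ANOVA feature selection, and
    grid-searched 10-fold cross-validated classification (random forest,
    linear support-vector and multi-layer-perceptron classifiers) across all
    sensor-fusion combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    signal,
    Matrix,
    splines,
    jsonlite,
    ranger,
    e1071,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
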