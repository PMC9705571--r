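Package: pcgphase
Title: Heart-Sound Classification of Heart-Failure Decompensation Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for classifying chronic-heart-failure
    phonocardiograms into decompensated and recompensated phases from heart
    sounds alone. Provides a synthetic phonocardiogram generator with
    ground-truth state annotations, Butterworth band-pass filtering and RMS
    loudness normalization, duration-dependent hidden semi-Markov model
    segmentation of the four heart-sound states (S1, systole, S2, diastole)
    by Viterbi decoding, a 177-feature per-cycle catalogue with cyclic
    windowed aggregation to 354 features, mutual-information feature
    selection, a ten-classifier suite under subject-wise stratified
    cross-validation with recording-level majority voting, McNemar model
    comparison, and a cardiologist-baseline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rcpp,
    rpart,
    randomForest,
    e1071,
    xgboost,
    caret
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
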