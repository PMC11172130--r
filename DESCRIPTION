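Package: eegrade
Title: EEG Phase-Lag-Index Pipeline for Four-Level Anxiety Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for grading generalized anxiety disorder from
    resting-state EEG. Implements Phase Lag Index functional connectivity over
    four canonical rhythms and sixteen 10-20 electrodes, zero-phase Butterworth
    preprocessing and epoching at seven window lengths, combined cleaning and
    resampling (CCR) for class imbalance, gradient-boosted-tree classification
    with tree-structured Parzen estimator hyperparameter search, recursive
    feature elimination with early stopping, repeated stratified
    cross-validation with macro metrics, and brain-region/rhythm attribution of
    selected connectivity features. Includes a synthetic EEG cohort generator
    with planted band-specific phase-lag coupling so the full pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    e1071,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
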