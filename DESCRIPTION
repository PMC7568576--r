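Package: cardiowave
Title: Classification of Aortic Stenosis from Wearable Seismo- and
    Gyro-Cardiography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for classifying aortic stenosis
    from six-axis chest-worn inertial recordings (three-axis
    seismocardiogram and three-axis gyrocardiogram). Provides a synthetic
    cohort generator with subject-level random effects and motion
    artifacts, zero-phase band-pass filtering, RMS-median low-noise
    segmentation into fixed 10-s windows, a generalized Morse-wavelet
    continuous wavelet transform with per-frequency statistical feature
    extraction, elastic-net feature selection with frequency/statistic/
    source distribution summaries, grid-search-tuned decision-tree,
    random-forest, multi-layer-perceptron and gradient-boosting
    classifiers under leave-one-subject-out and leave-data-out
    validation, and a compact 2-D convolutional network over scalogram
    images together with an exact layer shape and parameter-count
    calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
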