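Package: rresp
Title: Mental-State Classification of Relaxation Responses from RR and
    EDA Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Windowed feature engineering and supervised-learning
    evaluation for classifying the mental context (relaxation, basal rest,
    stress) of relaxation-response episodes from heart inter-beat (RR)
    intervals and electrodermal activity (EDA).  Implements zero-phase
    low-pass preprocessing, 20-second sliding-window extraction of 50
    time-, frequency- and Poincare-domain features plus the adaptive
    RR_Band discretization, correlation-based feature selection with
    best-first search, a 12-classifier repeated stratified
    cross-validation harness, and classifier comparison via the Friedman
    test and the Bayesian correlated t-test with a region of practical
    equivalence.  Ships a seeded synthetic register generator so the whole
    pipeline is testable without physiological recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pracma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
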