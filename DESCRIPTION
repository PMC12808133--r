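Package: dcanet
Title: Dynamic Context-Aware Multi-Modal Networks for Longitudinal
    Parkinson's Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Longitudinal prediction of motor-UPDRS scores from
    at-home Parkinson's telemonitoring data. Reads the standard
    telemonitoring visit table (16 acoustic dysphonia measures plus
    demographics and UPDRS), engineers four per-timestep feature
    modalities (signal-processed voice biomarkers, lagged clinical
    progression markers, demographic metadata, and embedded clinical
    narrative summaries), and fits a dynamic context-aware network:
    per-modality encoders, multi-head dynamic attention fusion with
    learned convex modality weights, a causally masked temporal
    attention block over stacked bidirectional LSTMs, and a Huber-loss
    AdamW training loop. Includes a synthetic telemonitoring cohort
    generator with known ground truth, repeated patient-level k-fold
    cross-validation, a modality ablation runner, classical baseline
    comparators, and agreement/concordance statistics (Bland-Altman,
    Kendall's W).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    glmnet,
    optparse,
    pracma,
    ranger,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
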