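Package: bacterisk
Title: Uncertainty-Aware Bacteremia Risk Modelling and Reader-Study Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an uncertainty-aware bacteremia
    risk model on emergency-department data and for analysing its effect on
    physician predictions. Provides a synthetic cohort generator with a known
    logistic generative risk, preprocessing for mixed structured and free-text
    inputs (standardization, one-hot encoding, TF-IDF), a mean-field
    variational Bayesian neural network with Monte-Carlo predictive intervals,
    a dual AI/physician uncertainty taxonomy, discrimination and calibration
    metrics with DeLong and Wilson intervals, permutation-sampling Shapley
    feature importance, and multi-reader multi-case (Obuchowski-Rockette)
    comparison of pre- versus post-AI reader performance with weighted kappa
    and transition analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
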