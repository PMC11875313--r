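Package: nanotox
Title: Machine-Learning and PBPK-Based Prediction of Inorganic Nanoparticle Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A harmonized tabular pipeline for classifying in vitro cytotoxicity of
    inorganic nanoparticles from physicochemical descriptors, with nested
    cross-validation over gradient-boosted and randomized tree ensembles,
    PR-AUC-driven hyperparameter selection, a logistic stacking ensemble,
    Shapley-value explainability with SHAP-guided feature reduction, and partial
    dependence curve fitting. A six-compartment minimal physiologically-based
    pharmacokinetic (PBPK) model with nonlinear least-squares calibration
    converts organ biodistribution time series into time-averaged exposure
    metrics that extend the classifier to organ-specific in vivo toxicity.
    Includes a synthetic-data generator with planted ground truth so every
    pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    xgboost,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
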