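Package: aerosurf
Title: Ground-Level PM2.5 Exposure Surfaces from Sparse Monitors via
    IDW-Residualized Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts daily mean and daily 1-h maximum fine particulate
    matter (PM2.5) over a regular grid from hourly station observations and
    gridded predictor fields (aerosol optical depth, meteorology, land use).
    The estimator trains gradient-boosted trees with a log-cosh objective on
    residuals from an inverse-distance-weighted (IDW) interpolation of
    same-day observations and adds the interpolation back to the tree
    predictions.  Includes leakage-aware leave-one-station-out
    cross-validation with nested station-wise tuning over a maximin
    Latin-hypercube hyperparameter design, absolute-loss-first evaluation
    metrics, a seeded synthetic study-region generator, and exposure
    applications: regulatory-limit compliance with population weighting,
    heat co-occurrence, daily max:mean ratios, and areal deprivation
    linkage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lhs,
    rlang,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    igraph,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
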