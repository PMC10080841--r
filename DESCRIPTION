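Package: hastack
Title: Stacked Ensemble Forecasting of Daily Hospital Admissions with
    Label-Distribution-Smoothing Re-Weighting and Shapley Explanations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasts daily hospital admission counts from lagged
    admissions, air-quality, meteorological and calendar features using a
    two-phase stacking ensemble: four heterogeneous base learners (ridge
    regression, random forest, gradient-boosted trees, a feedforward
    network) produce chronological out-of-fold meta features that an
    elastic-net meta learner combines with pass-through key features.
    Label imbalance in the count target is countered by re-weighting the
    meta learner with the inverse of a kernel-smoothed ("effective") label
    density, stratified by calendar year.  Includes a synthetic daily-panel
    generator calibrated to a four-year urban admissions setting, a
    four-metric evaluation harness (MAE, RMSE, MAPE, R-squared) with paired
    t-tests, and a permutation Shapley explanation layer with grouped lag
    aggregation and a three-part additive decomposition of every forecast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    xgboost,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
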