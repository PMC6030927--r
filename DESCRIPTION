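Package: dynlandmark
Title: Two-Stage Dynamic Landmark Models for Risk Prediction from
    Repeated Measurements in Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic prediction of 10-year disease risk from sporadically
    recorded repeat risk-factor measurements in primary-care electronic
    health records.  Stage one fits, at each landmark age and separately by
    sex, a multivariate linear mixed-effects model with correlated random
    intercepts for smoking status, systolic blood pressure, total
    cholesterol and HDL cholesterol, and recovers error-free "current"
    risk-factor values for any individual by empirical-Bayes best linear
    unbiased prediction.  Stage two stacks the landmark datasets and fits a
    sex-stratified super-landmark Cox proportional hazards model with
    patient-clustered robust standard errors and a Breslow baseline hazard,
    from which 10-year risks are predicted.  Includes a synthetic EHR
    generator, cohort construction rules (entry/exit dates, plausibility
    filters, sex-specific standardization), comparator models (last
    observed, cumulative mean, basic, age interactions), and censoring-aware
    validation (Brier score, Harrell C-index, calibration deciles, 10-fold
    cross-validation split by practice).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
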