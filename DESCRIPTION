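Package: pmmi
Title: Reference-Based Multiple Imputation Sensitivity Analysis for
    Longitudinal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pattern-mixture sensitivity analysis for longitudinal
    clinical trials with missing outcome data.  Missing post-deviation
    outcomes are multiply imputed under missing-at-random (MAR) and four
    reference-based missing-not-at-random assumptions (jump to reference,
    copy increments in reference, copy reference, last mean carried
    forward), using Gibbs data augmentation for a per-arm multivariate
    normal imputation model.  Each completed dataset is analysed with a
    random-intercept linear mixed model and results are pooled with
    Rubin's rules.  Includes missingness-pattern bookkeeping and
    homogeneity tests, a longitudinal trial simulator with calibrated
    MCAR/MAR dropout, and a simulation-study driver reporting bias, RMSE
    and coverage for maximum likelihood and the imputation-based methods.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
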