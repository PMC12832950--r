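Package: surrometa
Title: Trial-Level Surrogate Endpoint Validation by Bivariate Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates candidate surrogate endpoints from trial-level summary
    data (hazard ratios with confidence intervals), with radiographic
    progression-free survival versus overall survival in first-line metastatic
    castration-resistant prostate cancer as the bundled worked example.
    Implements bivariate random-effects meta-analysis of paired log hazard
    ratios (restricted maximum likelihood with an empirical-Bayes shrinkage
    alternative), inverse-variance weighted linear regression, surrogate
    threshold effect estimation by inverting the regression band at the null,
    leave-one-out cross-validation of trial-level predictions, IQWiG
    correlation-strength classification, and a synthetic-data generator with
    known surrogacy structure for calibration and recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor,
    ggplot2,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
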