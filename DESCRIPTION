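Package: phewasmr
Title: Phenome-Wide Screening and Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for phenome-wide association scans (PheWAS) over
    phecode-grouped clinical diagnoses followed by two-sample Mendelian
    randomization (MR) causal estimation. Provides instrument loading and
    harmonization with strand-ambiguity resolution, genetic risk scores,
    phecode mapping with exclusion-range control groups, covariate-adjusted
    logistic and linear association scans, an MR power filter and
    Benjamini-Hochberg FDR control, and the full MR estimator and sensitivity
    suite: Wald ratios, multiplicative random-effects inverse-variance
    weighting, weighted median, MR-Egger with intercept test, SIMEX
    attenuation correction, Cochran's Q, I2GX, leave-one-out, multivariable
    MR, and sex-stratified analysis. A synthetic-cohort generator with
    configurable causal effects, pleiotropy, and case prevalences makes every
    stage testable without individual-level biobank data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
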