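Package: clpv
Title: Construct-Level Predictive Validity from Censored, Range-Restricted Selection Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates construct-level predictive validity (the true
    correlation between the trait measured by a selection test and the trait
    measured by a later outcome) from selection-study data in which the
    predictor is range-restricted by selection, attenuated by measurement
    error, and right-censored at a grade ceiling. Fits a seven-parameter
    censored bivariate-normal model to applicant and entrant data by maximum
    likelihood and by delayed-rejection adaptive Metropolis (DRAM) MCMC,
    applies the Hunter-Schmidt-Le indirect range-restriction correction to
    every retained draw to obtain estimates with standard errors and
    percentile intervals, back-calculates equivalent sample sizes, pools
    validities across studies by random-effects meta-regression, and makes
    closed-form predictions of out-of-range applicant performance (expected
    scores, failure and retake rates, grade-increment effects, and power
    calculations). Includes grade-tariff scoring utilities and a synthetic
    cohort generator reproducing the assumed generative structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    mvtnorm,
    metafor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
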