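Package: mistrat
Title: Misclassified Stratification Variables in Randomised Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte Carlo simulation machinery for studying how
    misclassification of a binary stratification covariate affects the
    analysis of randomised controlled trials with continuous outcomes.
    Simulates trials that use stratified permuted-block randomisation with
    stratum-specific misclassification of the stratification variable and
    (possibly arm-dependent) discovery of those errors; analyses each trial
    by linear regression with no adjustment or with adjustment for the
    randomisation, true or updated strata; and summarises repetitions into
    the standard simulation-study performance measures (bias, empirical and
    model-based standard errors, relative error in the model SE, coverage
    and rejection rates), each with its Monte Carlo standard error.
    Includes the full scenario grid of the underlying simulation study,
    analytic power calculations for the trial designs, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
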