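Package: physbattery
Title: Individual-Differences Analysis for Intuitive Physics Task Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying stable individual differences in intuitive
    physics ability from trial-level task batteries. Implements iterated
    split-half reliability with subject-shuffle permutation nulls, bootstrap
    confidence intervals for between-task correlations, cross-validated
    single-factor analysis on left-out trial halves, OLS residualization of
    battery scores on covariate tasks, difference-of-correlation bootstrap
    tests, and cross-validated battery compression by trial subsampling
    (short-form construction). Ships a latent-trait (guessing-floor logistic)
    generator of synthetic trial-level batteries with retained ground truth,
    so every stage is testable by parameter recovery and small-instance
    enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
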