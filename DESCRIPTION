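Package: vdthealth
Title: Occupational Health Surveillance Modelling for Video Display Terminal Employees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing periodic occupational health surveillance of
    administrative employees who work at video display terminals (VDTs).
    Provides a seeded generator of synthetic categorical exam-record cohorts
    calibrated to published class-conditional risk-factor frequencies, a
    discrete Bayesian-network engine (augmented naive Bayes structure
    learning, maximum-likelihood conditional probability tables, exact
    inference by variable elimination, one-way sensitivity analysis),
    proportion-based risk-factor screening, and an influence-diagram
    cost-utility evaluation of medical protocol strategies.
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
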