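Package: esccea
Title: Markov Cohort Cost-Effectiveness Analysis of First-Line Immunochemotherapy for Advanced Esophageal Squamous Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov cohort
    model for evaluating the cost-effectiveness of serplulimab plus
    chemotherapy versus chemotherapy alone in PD-L1-positive advanced
    esophageal squamous cell carcinoma. Provides Weibull survival
    extrapolation, reconstruction of pseudo individual patient data from
    digitized Kaplan-Meier curves with maximum-likelihood Weibull fitting,
    discounted cost and QALY accrual, ICER and incremental net monetary
    benefit decision rules, one-way deterministic sensitivity analysis with
    tornado ranking, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic two-arm trial
    generator for end-to-end testing. Ships the published per-cycle costs,
    utilities, and fitted Weibull parameters as the default configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    flexsurv,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
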