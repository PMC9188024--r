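Package: fullcycle
Title: Full-Annual-Cycle Integrated Population Models for Bird-Banding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fitting Bayesian full-annual-cycle integrated
    population models (IPMs) to constant-effort bird-banding data. Stage-one
    hierarchical models turn station-level adult captures and microage
    records into regional abundance and age-structure indices; a stage-two
    model couples a first-order Markovian gamma population process with a
    transient-corrected Cormack-Jolly-Seber survival model and log/logit-
    linear climate-covariate models of recruitment and survival. Includes
    seasonal climate-covariate construction (drought deficits, monsoon
    rainfall timing), climate-vegetation regressions, seasonal range
    geometry for tracking points, a synthetic-data generator with known
    ground truth for every stage, convergence diagnostics, and posterior
    predictive checks. MCMC runs in JAGS via rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
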