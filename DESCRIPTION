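Package: cullwelfare
Title: Bayesian Animal Welfare Analysis for Helicopter-Based Culling Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing animal welfare outcomes of helicopter-based
    shooting trials of wild ungulates. Provides encounter and post-mortem
    data schemas with validation, a synthetic trial-data generator with
    randomised-block ammunition assignment, an adaptive
    Metropolis-within-Gibbs sampler with highest-posterior-density
    intervals, Gelman-Rubin and DIC diagnostics, censoring-aware exponential
    time-to-event models with latent-time imputation and a derived
    total-time quantity, Bayesian logistic models for encounter outcomes,
    Poisson and binomial models for wound tracts and shotgun pellet
    accounting, and a simulation-based power analysis for log-normal
    total-time data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
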