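Package: niclust
Title: Bayesian Noninferiority Analysis and Cost-Minimisation for
    Cluster-Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian noninferiority analysis of
    cluster-randomised trials of school-based physical activity
    implementation support, and for cost-minimisation from the provider
    perspective. Implements derivation of noninferiority margins from a
    retained-effect proportion and a reference-trial bound,
    baseline-adjusted linear mixed models with one-step posterior
    predictive imputation of missing outcomes, longitudinal gamma-hurdle
    models for zero-inflated component outcomes, posterior probability of
    noninferiority, a posterior-predictive variance ratio (a Bayesian
    analogue of the intraclass correlation), convergence diagnostics
    (Gelman-Rubin statistic, effective sample size), non-parametric
    bootstrap uncertainty intervals for per-school delivery costs, and a
    synthetic-trial generator emulating teacher activity logbooks for
    testing the full pipeline.
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
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
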