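Package: mdinfer
Title: Statistical Inference for Molecular-Simulation Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigorous uncertainty quantification for observables derived from
    molecular-dynamics simulations. Provides Bayesian and frequentist
    estimation of transition rates from censored trajectory outcomes,
    Bayes-factor comparison of kinetics across conditions, free-energy
    estimation from non-equilibrium work values (Crooks/Bennett maximum
    likelihood) and from umbrella-sampling windows (multistate reweighting),
    autocorrelation and statistical-inefficiency diagnostics, replicate
    statistics, and finite-size-aware solvent analyses (Yeh-Hummer diffusion
    correction, excluded-volume radial distribution function normalization).
    Includes synthetic-data generators emulating the statistical structure of
    simulation output so every estimator can be validated by parameter
    recovery without running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
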