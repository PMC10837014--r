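Package: reactnorm
Title: Reaction Norms, Environment Subsetting, and Genomic Prediction of
    Phenotypic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying phenotypic plasticity in multi-environment
    trials and common garden experiments. Estimates reaction norms
    (intercept and slope) by Finlay-Wilkinson joint regression, evaluates
    the consistency of plasticity parameters across exhaustive subsets of
    environments, predicts reaction-norm parameters for untested genotypes
    with ridge-regression BLUP under within-subset and subset-to-whole
    cross-validation, computes growing-degree-day and photothermal-time
    environmental indices from daily weather, and simulates environmental
    variability across sites, years, and planting dates. Includes a
    synthetic-data generator (biparental inbred populations, linear
    reaction-norm phenotypes, sinusoidal-seasonal weather) so the whole
    pipeline is testable without external data.
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
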