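Package: sysobs
Title: Disambiguating System and Observer Effects in Multimodal Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative modelling tools for deciding whether two simultaneously
    recorded neural time series (for example high-frequency broadband power from
    microwires and macroelectrodes on the same depth electrode) differ because of
    their underlying dynamics or because of the device-specific nonlinear
    observation functions that produced them. Provides Stratonovich-consistent
    stochastic simulation of coupled latent linear systems with sigmoidal
    observers, scene-based exogenous driver construction, variational-Laplace
    model inversion with an extended-Kalman-filter likelihood, Bayesian model
    reduction with Savage-Dickey pinning, model-fit diagnostics with exclusion
    rules, and end-to-end synthetic validation and per-subject analysis
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
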