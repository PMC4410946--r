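Package: nmminvert
Title: Gradient-Free MCMC Inversion of a Single-Node Neural Mass Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation and fully Bayesian inversion of a single-node
    neural mass model of coupled pyramidal, spiny-stellate and inhibitory
    populations. Provides the nine-state delay-approximated ODE forward model
    (stiff BDF integration), a Gamma-prior/Gaussian-likelihood log-joint
    density, four gradient-free MCMC samplers (univariate slice sampling with
    stepping out, random-walk Metropolis, adaptive Metropolis with
    Robbins-Monro tuning of the proposal mean, covariance and scale, and
    population MCMC with tempered chains and replica exchange), fixed-point
    linear-stability analysis with a prior instability census, and
    chain-efficiency diagnostics based on the initial monotone sequence
    estimator of the effective sample size.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
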