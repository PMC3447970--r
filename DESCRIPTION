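Package: reachgain
Title: Expected-Gain Analysis of Obstacle-Avoidance Reaching
Version: 0.1.0
Authors@R: person("Motor Decision Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing speeded reaching around a costly virtual
    obstacle within Bayesian decision theory. Simulates blocked reach
    experiments with excursion-dependent motor noise, summarises crossing
    statistics at the obstacle and target planes, fits linear
    noise-versus-excursion models, computes maximum-expected-gain (MEG)
    excursions per condition, applies the Dominance Test to observed
    strategies, and scores unity-line agreement between observed and
    optimal excursions with a decibel evidence measure, alongside
    stationarity, autocorrelation and Gaussianity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
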