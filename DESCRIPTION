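Package: chickrl
Title: Opponent-Sensitive Reinforcement Learning in the Repeated Chicken Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of trial-by-trial
    learning models for the two-opponent repeated Chicken game. Provides the
    task environment (payoff matrices, programmed high- and low-competitive
    opponents, blocked and interleaved designs), a bank of twelve
    reinforcement-learning models (reward-based delta-rule learning,
    fictitious-play belief learning, second-order-belief learning, plus
    non-learning and preference-only baselines), non-centered hierarchical
    MCMC estimation with split-R-hat diagnostics, PSIS-LOO model comparison
    with stacking-based family aggregation, and validation tooling (posterior
    predictive checks, model recovery, parameter recovery) on synthetic
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
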