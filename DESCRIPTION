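Package: percbias
Title: Online Bayesian Estimation of Perceptual Biases in 2AFC Tasks
Version: 0.1.0
Authors@R:
    person("Percbias", "Developers", email = "percbias@example.org",
           role = c("aut", "cre"))
Description: Trial-by-trial Bayesian estimation of perceptual biases,
    separately from decision biases, in two-alternative forced-choice
    (2AFC) tasks with interleaved stimulus contexts.  Provides the
    hierarchical psychometric choice model (cumulative-Gaussian link
    with lapses), an MCMC sampler for the joint posterior over
    perceptual and decision biases, an online estimator that refits
    after every trial, a reward-allocation rule that places the reward
    boundary at the running estimate of the perceptual bias, a
    temporal-difference reinforcement-learning agent for comparing
    reward strategies, a multi-session hierarchical extension with a
    linear hyperprior on session covariates, a conventional
    empirical-bias-prior baseline, and a synthetic-data generator with
    block-randomized schedules, bias dynamics and serial choice
    dependence for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
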