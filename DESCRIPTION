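Package: hexlearn
Title: Hierarchical Gaussian Filter Modelling of Hostile-Expectation Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for probabilistic shooting-task
    ("hostile expectation") learning experiments. Implements a family of
    reinforcement-learning observer models (two- and three-level Hierarchical
    Gaussian Filters for binary outcomes, Rescorla-Wagner, Sutton K1,
    Kalman filter) with a decision-noise (unit-square sigmoid) response model,
    per-subject MAP estimation with Laplace model evidence, random-effects
    Bayesian model selection with exceedance probabilities, a behavioural
    statistics layer (repeated-measures contrasts, JZS Bayes factors,
    Benjamini-Hochberg FDR, correlation power, reliability, PCA),
    maximum-likelihood confirmatory-factor and MIMIC structural equation
    models with bootstrap intervals, and synthetic-cohort generators with
    known ground truth for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
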