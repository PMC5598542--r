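Package: avoidrl
Title: Reinforcement-Learning Modelling of Pavlovian Avoidance in Go/No-Go
    Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical model-based analysis of the
    approach-avoidance go/no-go task under alternating safe and
    threat-of-shock blocks.  Implements a family of seven Rescorla-Wagner
    learning models with Pavlovian approach and avoidance bias terms and a
    lapse-squashed softmax choice rule; fits them across subjects and
    conditions by hierarchical type-II maximum-likelihood
    expectation-maximization with per-unit Laplace approximations; compares
    models and population-prior partitions by integrated BIC; runs
    posterior predictive simulations; and tests group and condition
    effects on recovered parameters with two-tailed permutation tests.
    Includes a synthetic-cohort generator emulating the task design so the
    whole pipeline is testable without participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
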