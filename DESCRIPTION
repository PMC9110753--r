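Package: socialbandit
Title: Social Learning and Exploration in Spatially Correlated Multi-Armed Bandits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing collective search in spatially
    correlated multi-armed bandit tasks. Generates reward landscapes from a
    Gaussian-process prior with a radial-basis-function kernel on an 11 x 15
    grid, models choice behaviour with a Gaussian-process upper-confidence-bound
    policy extended by a kernel-shaped imitation bonus towards a partner's
    previous choice (the UCB+S model), simulates solo and paired searchers,
    fits the model family to trial logs by maximum likelihood with a seeded
    differential-evolution optimizer, compares models by AIC, runs parameter
    recovery studies, and computes the standard behavioral metrics
    (per-session performance, unique-choice proportions by phase, migration
    length, within-pair parameter convergence).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
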