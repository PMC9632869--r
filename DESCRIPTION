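Package: sepsisrl
Title: Risk-Aware ICU Treatment Policies via Categorical Distributional
    Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns and evaluates risk-aware treatment policies from
    ICU-style hourly trajectory data. Provides k-nearest-neighbour matrix
    completion under a missing-value dissimilarity with a penalty
    parameter, k-means state discretization selected by a coverage
    heuristic, an empirical Markov decision process patient simulator
    with absorbing recovery and death outcomes, synchronous speedy
    categorical distributional Q-learning on a fixed return support, and
    Monte-Carlo policy evaluation utilities. Includes a synthetic cohort
    generator with a known ground-truth MDP for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
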