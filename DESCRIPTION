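Package: bqlearn
Title: Bayesian Q-Learning Models of Uncertainty-Guided Choice Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial reinforcement-learning models for two-choice
    bandit tasks with performance-gated block changes. Implements standard
    Q-learning variants (original, forgetting, differential-forgetting) and
    Bayesian Q-learning variants that track a beta-distributed action-value
    posterior with a moment-matched forgetting kernel, an uncertainty bonus
    in the soft-max choice rule, and an analytically derived effective
    learning rate. Provides a task simulator that generates synthetic
    sessions under the adaptive block-change rule, maximum
    normalized-likelihood fitting with multi-start bounded optimization,
    2-fold cross-validation model comparison, and behavioral analyses of
    uncertainty-dependent choice and learning rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
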