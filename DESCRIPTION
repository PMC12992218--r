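Package: probcoherence
Title: Coherence Audits for Election Probability-Judgment Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs the 78-item election probability-judgment battery
    used to audit probabilistic coherence (marginal, conjunctive,
    disjunctive and conditional win probabilities over triplets of U.S.
    states), elicits complete response sets from pluggable responders --
    a coherent classical baseline, a finite-sample Bayesian sampler, a
    sequential quantum projection model, or an external chat backend --
    under a persona-initialisation plus bounded sliding-memory protocol,
    scores conjunction and disjunction fallacies (single and double) and
    violations of binary complementarity, and runs paired and Welch group
    comparisons between cohorts of scored participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
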