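Package: mmlprefs
Title: Bayesian Preference Inference from Observed Choices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers feature-based preferences from observed choices with a
    Mixed Multinomial Logit model: additive feature utilities, the
    Luce-Shepard (softmax) choice rule over option pools with token
    multiplicities, importance-sampling and grid posteriors over utility
    vectors under a Gaussian prior, posterior-predictive offer prediction,
    reaction-constrained generalization to hidden objects, and Bayesian
    comparison of a shared-preference model against an
    individual-preference model via Monte-Carlo marginal likelihoods.
    Includes scenario builders for four developmental-psychology choice
    experiments, a forward simulator of choice data with a
    parameter-recovery harness, and JSON-lines serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
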