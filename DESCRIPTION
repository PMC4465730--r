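Package: ppdce
Title: Design and Analysis of Partial-Profile Discrete Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for stated-preference studies that compare hypothetical
    outcome profiles on many attributes at once. Builds Bayesian D-optimal
    partial-profile choice designs by attribute-balanced assignment of
    constant attributes and coordinate-exchange optimization of the varying
    levels, simulates respondent populations and their multinomial-logit
    choice behavior, fits conditional (multinomial) logit models with
    subgroup interactions by maximum likelihood, ranks attributes by
    likelihood-ratio importance with reference-standardized marginal
    utilities, and aggregates utilities over outcome scenarios to compare
    policy alternatives such as healthcare payment reforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    ggplot2
Config/testthat/edition: 3
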