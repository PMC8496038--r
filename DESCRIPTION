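Package: regspec
Title: Occupancy Calculus, Multimeric Motifs, and Turnover Simulation for
    Regulatory Sequence Grammar
Version: 0.1.0
Authors@R:
    person("regspec", "maintainers", email = "regspec@example.org",
           role = c("aut", "cre"))
Description: Tests whether transcription-factor binding models with and without
    spacing-and-orientation constraints reproduce global properties of
    regulatory sequence: length, uniqueness, frequency, evolutionary turnover,
    and master-regulator dominance. Provides position-matrix data structures
    and information content, construction of 3-6-TF multimeric motifs by
    chaining dimeric motifs, an exact p-value-to-threshold PWM scanner,
    the closed-form occupancy and Poisson specificity calculus, a hit-count
    logistic-regression classifier of regulatory versus background sequence
    with chromosome-held-out evaluation, neutral-mutation turnover
    simulations, and a fully seeded synthetic-data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    jsonlite,
    withr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
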