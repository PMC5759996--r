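Package: catbound
Title: Simulation and Decision-Bound Modeling of Cross-Modal
    Information-Integration Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing two-dimensional
    information-integration category-learning experiments with cross-modal
    (visual pixel-density by auditory tone-frequency) stimuli. Provides the
    generative two-category bivariate-Gaussian stimulus model with
    per-participant exemplar-set normalisation, analytic accuracy of linear
    decision boundaries and an optimal-boundary search, synthetic observers
    that respond through noisy decision-bound strategies across a multi-phase
    learning/test design with delay-group effects, maximum-likelihood fitting
    of four decision-bound model families (unidimensional, conjunction,
    general linear classifier, random) with AIC strategy classification, and
    a covariate-adjusted (ANCOVA) group analysis pipeline with type-I-error
    and parameter-recovery harnesses.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
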