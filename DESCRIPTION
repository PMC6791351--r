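Package: phylomiss
Title: Missing-Taxa Sensitivity of Trait-Evolution Model Selection and
    Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework to study how missing taxa affect
    model selection and parameter estimation for univariate continuous
    trait evolution on phylogenies. Simulates pure-birth trees, binary
    selective regimes under an equal-rates Mk model, and traits under
    single- and multi-regime Brownian Motion and Ornstein-Uhlenbeck
    models; generates random, phylogenetically clumped, and
    trait-correlated missing-taxa patterns; quantifies the phylogenetic
    signal of sampling status with the Fritz-Purvis D statistic; fits
    BM, BMS, OU and OUM by maximum likelihood with AICc model
    selection; and summarises model-selection error rates and the bias
    and precision of parameter estimates across replicated experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
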