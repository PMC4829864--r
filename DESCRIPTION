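Package: islandpcm
Title: Phylogenetic Comparative Tests of Island Effects on Trait Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether island lineages evolve phenotypes at
    different tempos and to different extents than their continental
    relatives. Implements single-rate and multi-rate Brownian motion and
    single-optimum Ornstein-Uhlenbeck trait models with AICc comparison,
    stochastic character mapping of island/continent regimes under Mk
    models, simulation-based phylogenetic ANOVA and MANOVA, morphological
    disparity ratio and pseudo-community null tests, parametric bootstrap
    tests of rate shifts with power estimation, and independent-contrast
    envelopes through time, together with a synthetic data generator that
    emulates a mainland-island radiation with island rate shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
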