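Package: phylosink
Title: Inferring the Evolutionary Model of Community-Structuring Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the effective-tree transformation parameter governing the
    evolution of unobserved community-structuring traits from species
    presence/absence data ordered on a phylogeny. Provides two estimators:
    Convolutional Kitchen Sinks (random convolutional features with ridge
    regression) and linear models on curves of standardized mean pairwise
    phylogenetic distance (MPD) computed across a gradient of early-burst or
    delta tree transformations. Includes the full simulation framework used to
    train and validate the estimators: forward birth-death tree simulation,
    exponential (early/late burst) and delta branch-length transformations,
    Brownian-motion trait simulation on effective trees, and trait-based
    community assembly by deterministic filtering, probabilistic filtering, or
    limiting similarity, plus bootstrap confidence intervals for empirical
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
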