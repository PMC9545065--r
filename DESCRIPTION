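Package: elevtraits
Title: Macroevolution of Plant Trait Divergence Across Elevational Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how plant traits diverge between low- and
    high-elevation species on a time-calibrated phylogeny. Fits and compares
    five trait-evolution models (white noise, single- and multi-rate Brownian
    motion, single- and multi-optimum Ornstein-Uhlenbeck) with species-mean
    measurement error, reconstructs binary elevational regimes by stochastic
    character mapping under 2-state Markov models, selects models by
    small-sample AICc consensus across maps, estimates phylogenetic half-life
    with bootstrap significance, fits maximum-likelihood phylogenetic linear
    mixed models for treatment-by-elevation effects, screens multivariate
    trait trade-offs (variance-inflation pruning, discriminant analysis of
    principal components, Pearson correlations), derives logistic
    growth-curve traits and stress tolerances from individual plant records,
    and generates fully synthetic trees, regime histories and experimental
    designs so every analysis stage can be validated by simulation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
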