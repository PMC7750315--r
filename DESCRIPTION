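Package: pollicolor
Title: Pollinator Vision Modeling and Phylogenetic Comparative Analysis of
    Floral Reflectance
Version: 0.1.0
Authors@R:
    person("Pollicolor", "Developers", email = "pollicolor@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing flower colour evolution through the eyes of
    pollinators. Reads and preprocesses corolla reflectance spectra (trimming,
    local-regression smoothing, averaging, binning), maps spectra into the
    perceptual spaces of a trichromatic nocturnal hawkmoth (Maxwell triangle,
    receptor-noise-limited chromatic and achromatic contrast) and of flies
    (categorical opponency model with Euclidean conspicuousness), quantifies
    group discriminability by bootstrap and permutation tests, and performs
    phylogenetic comparative inference: Brownian-motion, Ornstein-Uhlenbeck
    and early-burst model fitting with AICc, maximum-likelihood ancestral
    states, Mk discrete-trait models, stochastic character mapping, a Bayesian
    threshold model for ordered environmental zones, and phylogenetic
    generalized least squares between environmental liabilities and perceptual
    colour vectors. A synthetic-data generator produces reflectance spectra,
    Yule trees and trait histories with the statistical structure the analysis
    assumes, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
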