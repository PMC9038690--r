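Package: nitrex
Title: Agent-Based Simulation and Spatial Quantification of Nitrite
    Cross-Feeding Range Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates colony range expansion of a two-strain nitrite
    cross-feeding consortium (a nitrate-reducing producer and a
    nitrite-reducing consumer) on a hexagonal lattice under alternating
    anoxic/oxic conditions, with Monod growth kinetics, nitrite-inhibited
    biomass yields, finite-volume nutrient diffusion, and an edge-directed
    cell shoving algorithm.  Provides spatial pattern metrics for labeled
    colony rasters (edge-ring consumer:producer ratio, intermixing index,
    spatial jackpot event counts), a two-phase linear regression and
    transition-stability statistics layer, and ground-truth synthetic data
    generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
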