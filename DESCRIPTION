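Package: lexokin
Title: Two-Metal-Ion Kinetics of Processive DNA Degradation by Lambda Exonuclease
Version: 0.1.0
Authors@R:
    person("lexokin", "maintainers", email = "lexokin@example.org",
           role = c("aut", "cre"))
Description: Kinetic modelling and inference for the two-metal-ion (MgA/MgB)
    catalytic cycle of lambda exonuclease. Provides closed-form mean
    degradation velocities for the sequential-dissociation and
    coincident-dissociation reaction schemes, a position-resolved chemical
    master equation with first-passage-time densities of the N-nucleotide
    degradation time, quenched-disorder averaging and log10-velocity
    transforms, exact stochastic (Gillespie) simulation of translocation
    trajectories with synthetic smFRET trace generation and pause extraction,
    and an estimation pipeline: velocity-curve fitting (mechanistic,
    Michaelis-Menten and Hill), disorder-width estimation, and grid-search
    recovery of the slow metal-ion dissociation rate from log-velocity
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
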