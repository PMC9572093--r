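Package: oxiqspr
Title: QSPR Consensus Models and Inhibited-Oxidation Kinetics for Antioxidant
    Rate Constants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating and modelling the antioxidant chain-termination
    rate constant k7 of phenolic inhibitors. One arm analyses oxygen-uptake
    kinetics of initiated radical-chain oxidation: initiation rate from the
    initiator decay law, initial rates from kinetic curves, the dimensionless
    inhibition parameter F = V0/V - V/V0 and its linear concentration dependence
    yielding the effective constant f*k7, induction periods yielding the
    stoichiometric coefficient f, and k7 = f*k7/f with propagated uncertainties.
    The other arm builds quantitative structure-property models of log10(k7):
    multilevel neighborhood-of-atoms (MNA) substructural descriptors with
    whole-molecule descriptors, self-consistent regression with optional
    radial-basis refinement, consensus ensembles with an applicability domain,
    rank-ordered train/test splitting, and an external-validation metric battery
    (R2 variants, rm2, CCC, Q2F1/Q2F2, MAE-based quality classification).
    Synthetic-data generators with known ground truth support parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
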