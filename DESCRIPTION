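Package: octherapy
Title: Optimal Control of Combination Therapy for Heterogeneous Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the treatment response of heterogeneous cell
    populations to combinations of mutually interacting drugs using a
    semi-linear system of ordinary differential equations with
    multiplicative (bilinear) control and pairwise drug-synergy terms.
    Provides the associated finite-horizon optimal control machinery:
    Hamiltonian, adjoint equations, box-constrained stationarity
    conditions and a collocation solver for the coupled state-costate
    boundary value problem. Ships fully parameterised example systems (a
    two-compartment cell-cycle model treated with cisplatin and
    paclitaxel, and a three-compartment neuroblastoma differentiation
    model treated with retinoic acid, chemotherapy, a pan-trk inhibitor
    and NGF), a variant of the framework that controls cell-type
    proportions instead of counts, treatment-comparison statistics such
    as the efficacy ratio against constant dosing, parameter-space
    sweeps, and Monte-Carlo robustness analysis of optimal dosing
    schedules under temporally correlated dosing noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
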