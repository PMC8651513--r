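Package: recharge
Title: Regularized Partial-Charge Refinement and Interfacial Observables for
    Neutral Lipid Models
Version: 0.1.0
Authors@R: person("recharge", "maintainers", email = "recharge@example.org",
    role = c("aut", "cre"))
Description: Tools for refining atomic partial charges of neutral lipids
    (triacylglycerols, diacylglycerols) against interfacial-tension,
    surface-tension and density targets by thermodynamic reweighting of
    sampled ensembles, with confidence-interval-overlap stopping and hard
    per-cycle caps on charge changes. Includes the trajectory observables
    used to diagnose and validate such models: Kirkwood-Irving tension from
    pressure-tensor series, oil-core water content and equilibration
    detection, lateral density profiles and Boltzmann-inversion potentials
    of mean force with flip-flop barrier extraction, and glycerol-ester
    fragment dipole analysis. A self-contained Metropolis Monte Carlo
    sampler for charged Lennard-Jones systems provides an MD-free test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
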