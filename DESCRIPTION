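Package: haptosim
Title: Stochastic Simulation and Analysis of Multivalent Haptotaxis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained reaction-diffusion simulation of a
    receptor-decorated rigid disk adhering to a ligand-coated surface
    through reversible DNA bridges, and the statistical machinery to
    quantify its directed drift along a ligand-density gradient
    (haptotaxis). Includes DNA nearest-neighbor hybridization
    thermodynamics for sticky-end rate constants, inhomogeneous Poisson
    sampling of ligand carpets, a Gillespie bridge-kinetics engine
    alternating with uniform resampling of the disk centre inside the
    bridge-constrained feasible region, trajectory statistics
    (gradient-projected displacements, drift-velocity fits, diffusion
    coefficients, mobility filtering, size binning), and closed-form
    theory for the reaction-limited regime.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
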