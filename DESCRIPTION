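Package: cryovessel
Title: Cryosurgery Bioheat Simulation Near Bifurcated Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-dimensional transient simulation of cryosurgical freezing in
    perfused tissue surrounding a large bifurcated artery. Solves the Pennes
    bioheat equation with an effective (apparent) heat capacity treatment of the
    tissue phase transition, conjugately coupled to steady laminar blood flow in
    a parametrically generated arterial bifurcation, on a uniform Cartesian
    voxel grid with an implicit finite-volume scheme. Includes analytic
    verification oracles (two-phase Neumann-Stefan freezing front, semi-infinite
    conduction), metrics for iceball and lethal-zone volumes, artery-surface
    heat flux and vessel-injury treatment time, and drivers for probe-placement,
    inlet-velocity and multi-probe parameter studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
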