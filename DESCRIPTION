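Package: nanopost
Title: Coarse-Grained Polymer Chains Confined in Nanopost Arrays
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for flexible and semiflexible
    (DNA-like) bead-spring chains confined in a square-lattice array of
    parallel nanoposts. Implements the repulsive WCA + FENE + discrete
    worm-like-chain force field in reduced units, the array-geometry calculus
    (passage width, quasi-channel diameter, post volume fraction), NVT
    dynamics (Nose-Hoover or Langevin thermostats) and an equilibrium Monte
    Carlo sampler, conformational observables (occupation number, axial span,
    gyration tensor, bond-orientation correlations, single-chain structure
    factor), and the quasi-channel/quasi-slit confinement free-energy theory
    (Odijk and de Gennes regimes) used to interpret chain partitioning among
    interstitial volumes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
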