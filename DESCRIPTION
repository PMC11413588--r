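Package: spheroidCPM
Title: Cellular Potts Simulation of Depth-Zone Chondrocyte Spheroid Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-dimensional Cellular Potts Model (CPM) of spheroid and
    cell-cluster formation by articular chondrocytes isolated from the surface
    (SZ), middle (MZ) and deep (DZ) cartilage depth zones. Compartments (cells
    and two classes of extracellular matrix, structural ECMst and volumetric
    ECMv) evolve on a voxel lattice by Metropolis index-copy dynamics under a
    contact-energy plus volume-constraint Hamiltonian, coupled to a cyclic
    lifecycle of cell growth, mitosis, stochastic ECM secretion, ECM decay and
    deletion. Includes zone-specific parameter tables, translation of relative
    gene-expression quantities into model parameters, cylindrical seeding
    geometries, and morphometric readouts (connected clusters, projected
    diameters, diameter ratios, radial core-shell profiles) used to compare
    simulated morphology with in vitro spheroids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
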