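Package: motorscape
Title: Coarse-Grained Actomyosin Energy Landscapes and Stepping Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-scale simulation toolkit for the actomyosin motor. Builds
    residue-level Go-type models of myosin S1 on a helically symmetric actin
    filament, evaluates the structure-based potential (bond angles, dihedrals,
    12-10 native contacts, excluded volume, ligand restraints, Debye-Hueckel
    electrostatics, 12-6 van der Waals, curtain-rail and anchor restraints),
    samples the motor-domain position by underdamped Langevin dynamics with
    RATTLE bond constraints under umbrella biases, reconstructs two-dimensional
    free-energy landscapes in cylindrical coordinates by WHAM with helical data
    replication, and simulates biased Brownian stepping by Metropolis Monte
    Carlo on a switching set of state-dependent landscapes with an absorbing
    rigor state. Includes generators for desk-scale synthetic mini-systems and
    landscape sets, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
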