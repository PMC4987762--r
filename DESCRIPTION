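Package: efunnel
Title: Grid Electrostatics and Binding-Energy Funnel Analysis for
    Motor-Filament Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-scale continuum electrostatics for rigid-body
    recognition between a small motor domain ("probe") and a charged
    filament. Provides a finite-difference zero-salt Poisson solver on
    regular grids with a two-dielectric map, dipole boundary conditions
    and computational focusing; Coulombic/reaction-field energy
    decomposition and electrostatic binding energies; cylindrical and
    planar rigid-body pose sampling reduced to two-dimensional
    minimum-energy funnel maps; electrostatic force and
    work-of-detachment estimation on charge-silenced probes; trajectory
    hinge detection from Calpha segment angles and salt-bridge
    occupancy; alanine charge-neutralisation scans; and a linear model
    linking electrostatic binding energy to single-molecule motility
    phenotypes. Includes seeded generators for synthetic probe, binding
    surface, hinged-trajectory and phenotype data with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    graphics,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
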