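Package: sproutfield
Title: Phase-Field Simulation of Chemotactic Endothelial Sprouting Through
    a Porous Extracellular Matrix
Version: 0.1.0
Authors@R:
    person("Sproutfield", "Developers", email = "sproutfield@example.org",
           role = c("aut", "cre"))
Description: Conserved phase-field (Cahn-Hilliard) simulator of sprouting
    endothelial cells migrating through a porous hydrogel extracellular
    matrix under a chemotactic gradient. The cell environment (chemoattractant
    plus matrix density) is composed into a single coupling field acting on
    the diffuse cell interface. Includes Dirichlet cell reservoirs, an
    extension in which the leading tip cell senses the matrix and degrades it
    with a Gaussian matrix-metalloproteinase footprint, synthetic porous-ECM
    generation calibrated to a target mean pore size, local-thickness pore
    morphometrics, tip tracking and volume-flux metrics, scenario builders
    for the canonical in-silico experiments, and a command-line interface
    for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
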