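Package: bolasim
Title: Coarse-Grained Simulation and Mechanics of Bolalipid and Bilayer Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implicit-solvent coarse-grained molecular dynamics of lipid
    membranes built from single-headed bilayer lipids and membrane-spanning
    double-headed bolalipids, in the bead-spring tradition of the Cooke-Deserno
    model. Provides seeded builders for flat membranes, dispersed gases,
    cylinders, free patches and adhesive cargo setups; a Langevin integrator
    with a zero-lateral-tension barostat; and the analyses used to
    characterise such membranes: per-lipid conformation statistics (U-shaped
    versus straight bolalipids), diffusion and gel/liquid/gas phase
    classification, height-fluctuation spectra fitted with a tilt-corrected
    Helfrich model, curvature-dependent bending rigidity from membrane tubes,
    the Gaussian bending modulus from patch-closure ensembles, cargo-wrapping
    onset adhesion energies, and probe-sphere detection of transmembrane
    pores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
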