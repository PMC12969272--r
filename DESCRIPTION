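Package: bilayertools
Title: Membrane Bilayer Trajectory Analysis and Synthetic Ground-Truth Generation
Version: 0.1.0
Authors@R:
    person("Membrane", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of lipid
    bilayers with small-molecule solutes: area per lipid from the periodic
    box, phosphate-to-phosphate membrane thickness, the C-H (deuterium)
    order parameter, segment-based lateral diffusion coefficients from mean
    square displacement, Boltzmann-inversion free-energy profiles with
    per-leaflet folding, flux-based permeability coefficients from complete
    leaflet-to-leaflet crossing events, and a grouped lipid
    enrichment/depletion index for lateral mixing.  A companion
    synthetic-trajectory generator produces bilayer trajectories with known
    diffusion coefficients, order parameters, free-energy profiles and
    crossing rates (overdamped Langevin dynamics), so that every estimator
    is validated by parameter recovery and closed-form limits without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
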