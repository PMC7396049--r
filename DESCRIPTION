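Package: aquaflux
Title: Water Permeation Analysis for Channel-Protein Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for water permeation through membrane channel
    proteins (aquaporins and relatives) from molecular dynamics trajectories:
    time-averaged water density profiles along the channel axis, Boltzmann
    inversion of the density into a free-energy profile with thermal (kBT)
    error propagation and barrier extraction, single-file water-wire
    detection, pore-radius profiling with selectivity-filter localization,
    zoning of pore-lining residues, and RMSD-based equilibration detection.
    Includes a seeded synthetic-trajectory generator (inverse-CDF Boltzmann
    sampling and a 1-D overdamped Langevin integrator) so every stage is
    testable by parameter recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
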