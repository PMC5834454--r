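Package: npcmimic
Title: Coarse-Grained Simulation and Conductance Modelling of DNA-Origami
    Nuclear-Pore Mimics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying artificial nuclear-pore-complex mimics built
    from DNA-origami rings carrying grafted FG-nucleoporins. Provides a
    one-bead-per-amino-acid force field for intrinsically disordered proteins
    (hydrophobicity-scaled Lennard-Jones pair attraction, Debye-screened
    electrostatics, stiff harmonic bonds), a Langevin dynamics engine for
    chains tethered inside a ring scaffold docked on a solid-state nanopore,
    time-averaged 3D mass-density grids with cylindrical reductions, a
    density-based ion-conductance model with separate pore and access
    resistance terms, analysis of nanopore current traces (Gaussian low-pass
    filtering, docking-event level detection, blockade statistics, IV fits),
    photobleaching step counting by change-point detection, and seeded
    synthetic-data generators for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
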