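Package: oxdock
Title: Docking-Pose Triage and Enantioselectivity Analysis for Aldoxime
    Dehydratases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Post-processing pipeline for protein-ligand docking studies of
    aldoxime dehydratases (Oxd), heme enzymes that dehydrate aldoximes to
    nitriles and kinetically resolve racemic E- and Z-aldoximes with opposite
    enantiopreference.  Provides geometric pharmacophore validation of docked
    poses against the catalytic binding motif (heme-Fe coordination, Ser/His
    hydrogen bonds), E/Z and R/S stereochemical bookkeeping, conversion of
    binding-energy differences (ddG) between enantiomer pairs into predicted
    enantiomeric ratios (E-values) via transition-state theory, computation of
    experimental E-values from conversion and product enantiomeric excess
    (Chen-Sih relation), concordance reports between predicted and observed
    enantiopreference, and a synthetic-data generator that simulates
    competitive first-order kinetic resolutions and fabricates pose ensembles
    and docking tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
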