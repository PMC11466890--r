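Package: chirassign
Title: Absolute Configuration Assignment from Computed NMR and ECD Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for the computational assignment of
    absolute configuration in natural products with isolated blocks of
    chirality. Provides molecular-formula arithmetic for high-resolution
    mass spectrometry (monoisotopic and adduct masses, ring-plus-double-bond
    equivalents, formula search), Boltzmann weighting of conformer ensembles
    with energy-window and population-floor filters, linear scaling of
    computed isotropic shieldings to chemical shifts with stereoisomer
    ranking against experimental shift tables, Gaussian broadening of
    electronic circular dichroism stick spectra with global and region-wise
    similarity scoring, combination of relative-configuration and ECD
    evidence into full stereodescriptors, and docking-pose RMSD clustering
    with a largest-cluster in-pocket validity rule. Seeded synthetic-data
    generators emulate quantum-chemistry and docking outputs so the whole
    pipeline is testable without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
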