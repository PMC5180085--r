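Package: mwpife
Title: Steady-State Protein-Nucleic Acid Binding Analysis from Microwell PIFE Plates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for microwell protein-induced fluorescence
    enhancement (mwPIFE) assays of protein-nucleic acid binding. Reads and
    validates plate layouts and multi-scan well fluorescence tables, computes
    control-corrected PIFE statistics with replicate dispersion and condition
    comparisons, models equilibrium binding under ligand depletion (quadratic
    isotherm) and competitive displacement by mass action, estimates
    dissociation constants by nonlinear least squares with bootstrap
    confidence intervals, and ships a generative synthetic plate simulator
    (occupancy-dependent enhancement, dye-distance falloff, photobleaching,
    cleavage/wash signal loss, multiplicative noise) with presets emulating
    restriction-enzyme, Ku and XPF/ERCC1 experiment designs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
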