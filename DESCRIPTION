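Package: spindlescreen
Title: Sensitized RNAi Screen Analysis for Multipolar Spindle Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for sensitized (double-perturbation)
    high-content RNAi screens of mitotic spindle assembly. Provides a
    synthetic fluorescence-microscopy simulator with per-cell ground truth,
    per-cell image analysis (nucleus segmentation, phospho-histone H3 mitotic
    gating, RFP cytoplasm segmentation, quality-control filters, spindle-pole
    spot detection and phenotype classification), per-well feature extraction,
    plate-normalized Z and differential-Z scoring with hit calling,
    uncentred-Pearson complete-linkage phenotypic clustering with
    Cluster-3.0/TreeView export, and multiplicative genetic-interaction
    scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
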