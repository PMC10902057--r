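Package: lipidseg
Title: Lipid Imaging Mass Spectrometry Segmentation and Fingerprint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for lipid imaging mass spectrometry (LIMS/MSI)
    of focally demyelinated spinal cord tissue. Provides spectral
    preprocessing (ppm alignment, total-ion-current normalization,
    average-spectrum peak picking, datacube reduction), divisive
    hierarchical clustering with rank-competing random walkers (DHC-RC)
    for correlation-driven image segmentation with recursive
    re-segmentation of selected segments, region lipid-fingerprint
    statistics (Welch t-tests with star coding, PCA, random-forest
    classification with leave-one-section-out cross-validation), and
    negative-mode [M-H]- lipid annotation against a bundled library.
    Includes a ground-truth-labelled synthetic MSI datacube generator
    emulating lysolecithin-lesioned mouse spinal cord sections, and
    imzML import/export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    xml2,
    jsonlite,
    randomForest,
    png
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
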