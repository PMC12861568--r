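Package: xpct
Title: Simulation and Quantitative Densitometry for X-Ray Phase-Contrast
    Virtual Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end simulation and analysis pipeline for
    propagation-based x-ray phase-contrast tomography (XPCT) of
    paraffin-embedded neural tissue. Generates three-dimensional
    electron-density phantoms of neurodegenerative inclusions (Lewy
    bodies, Hirano bodies, granulovacuolar degeneration, amyloid
    plaques, neuromelanin clusters), simulates multi-distance
    holographic acquisition in the Fresnel regime, retrieves phase by
    CTF, Paganin or nonlinear Tikhonov schemes, reconstructs by
    filtered back projection, calibrates electron density against the
    paraffin embedding, and quantifies per-structure density
    distributions with Mann-Whitney/Bonferroni statistics, watershed
    and threshold segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
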