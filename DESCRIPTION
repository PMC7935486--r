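Package: erkwave
Title: Mechanochemical ERK Waves and Tissue-Flow Quantification in the
    Developing Cochlear Duct
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image-quantification toolkit for studying
    retrograde ERK activation waves and multicellular flow during murine
    cochlear-duct outgrowth. Implements a one-dimensional mechanochemical
    cell-chain model (viscous junction dynamics, strain-activated ERK,
    ERK-driven contractility) in both closed-feedback and imposed-wave
    regimes, with cross-correlation lag analysis of extension-shrinkage and
    ERK activity rates; a FRET/CFP ratiometric pipeline with window-based
    particle image velocimetry, flow projection onto the apex-base line, and
    per-window strain and ERK rates; kymography and traveling-wave speed
    estimation; cubic-spline curvature and thickness morphometry of traced
    epithelial layers; regional EdU intensity mapping and cell-density
    tables; and seeded synthetic-data generators (textured wave movies and
    geometric phantoms) carrying analytic ground truth for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
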