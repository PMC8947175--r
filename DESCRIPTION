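Package: ectopuncta
Title: Semi-Quantitative Detection of Ectopic Mitochondrial DNA Puncta in
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects and counts cytoplasmic (mitochondria-derived) double-
    stranded DNA puncta in triple-stained fluorescence microscopy images
    (dsDNA, histone H2B, Hsp60).  Implements calibrated channel subtraction
    (scaling factors estimated from control images so that the scaled
    subtraction drives the corresponding DNA signal to zero), thresholding,
    connected-component shape filtering by area and circularity,
    topological exclusion of ring-shaped ("donut") nuclear-origin
    structures, histone-overlap classification, nucleus counting for
    per-cell normalisation, and group statistics.  Includes a synthetic
    multi-channel image generator with ground truth for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
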