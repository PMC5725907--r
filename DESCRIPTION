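Package: sproutr
Title: Quantification of Bead-Sprouting Angiogenesis Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of fibrin-gel bead sprouting
    angiogenesis images. Detects microcarrier beads, segments the vascular
    sprouts attached to them, skeletonizes the sprout network to measure
    sprout number, length, width and branch points, detects and classifies
    cell nuclei into endothelial cells and pericytes from a nuclear
    endothelial marker, and measures pericyte coverage from a pericyte
    surface marker. Includes plate-screening statistics (bead-count weighted
    well aggregation, solvent-matched control normalization, one-sample
    t-tests) and a synthetic multi-channel image generator with exact ground
    truth for benchmarking every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
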