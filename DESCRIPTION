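Package: colonysim
Title: Agent-Based Simulation of Bacterial Microcolonies with Synthetic
    Microscopy Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional monolayer bacterial microcolonies with
    an agent-based model (polygonal cell outlines, exponential single-cell
    growth, phenomenological 'timer'/'sizer' size-homeostasis division rules,
    rigid-body overlap resolution) and synthesizes realistic phase-contrast
    and fluorescence microscopy frames together with pixel-accurate ground
    truth: YOLO detection boxes, COCO instance polygons, 16-bit label masks,
    TrackMate-style lineage XML and watertight STL meshes for computational
    fluid dynamics. Intended for generating training data for deep-learning
    segmentation and tracking of microbes in microfluidic live-cell imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    xml2,
    yaml,
    tiff,
    png,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
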