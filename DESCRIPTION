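Package: histocyto
Title: Headless Histo-Cytometry of Segmented Tissue-Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable histo-cytometry engine for multi-channel tissue-section
    images that have been segmented into per-cell regions. Reads and writes the
    four-file interchange bundle used by ImageJ/Fiji-based segmentation pipelines
    (multi-page TIFF image, zip archive of ImageJ .roi polygon contours, per-cell
    results CSV, channel legend CSV), natively re-measures membrane-ring channel
    intensities and morphology from labeled nucleus z-stacks, flags cells by
    density-based (DBSCAN) tissue regions and by contact with partner cells, and
    provides a flow-cytometry-style gating engine (range filters, rectangle,
    quadrant and lasso gates, threshold symbol classes, population statistics,
    gate persistence, annotation edits) together with image-overlay rendering of
    gated populations and a ground-truth synthetic bundle generator.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    grDevices,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
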