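Package: spattile
Title: Tiled Image Pyramids and Lazy Feature Stores for Spatial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, writes, and lazily reads multiscale tiled image
    pyramids in the cloud-optimized GeoTIFF layout, so that viewers can
    fetch single tiles with plain byte-range reads from disk or over
    HTTP. Companion tools encode per-spot or per-cell feature matrices
    (for example gene expression) as sparse, chunked, compressed stores
    that support single-feature lazy reads, bind images, spatial
    overlays and feature groups into a self-describing Sample folder,
    convert 10x Genomics Visium Space Ranger and Vizgen MERFISH outputs
    into that layout, and import/export region annotations as CSV and
    GeoJSON. Deterministic synthetic fixtures for every supported input
    format are included so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    Matrix,
    methods,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
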