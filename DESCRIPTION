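Package: ecosecpat
Title: Landscape Ecological Security Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for constructing landscape ecological security patterns
    on raster landscapes: morphological spatial pattern analysis (MSPA) of
    ecological land into core, islet, perforation, edge, loop, bridge and
    branch classes; graph-theoretic habitat connectivity indices (IIC, PC,
    dIIC, dPC) and ecological-source selection; analytic hierarchy process
    (AHP) weighting with consistency checking and weighted-overlay
    resistance surfaces; minimum-cumulative-resistance cost distance and
    least-cost ecological corridors with redundancy pruning; D8 ridgeline
    extraction and ecological-node identification. Includes a seeded
    synthetic-landscape generator emulating arid-region land cover, NDVI,
    terrain and infrastructure so the full pipeline runs end-to-end without
    external geodata, plus ESRI ASCII grid and single-band GeoTIFF I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
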