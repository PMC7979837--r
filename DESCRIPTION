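Package: spotcells
Title: Single-Cell RNA Counting, Neighbour Detection and Local Expression
    Variability from 3D FISH Spot Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-segmentation analysis of single-molecule FISH experiments in
    early embryos. Builds per-cell 3D convex polygons from membrane-channel
    spot clouds, detects immediately neighbouring cells by Minkowski expansion
    and intersection of the polygons (or by a centroid radius search), assigns
    transcript spots to cell volumes from their 3D coordinates, and computes
    per-cell local expression-variability statistics (Fano factor, numerical
    variability NV and proportional variability PV) over immediate-neighbour
    groups, with the associated count histograms and spatial heatmaps. A
    synthetic blastoderm-embryo generator with stripe and broad-domain
    expression patterns provides ground truth for every pipeline stage.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    quadprog,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
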