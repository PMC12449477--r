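Package: perizone
Title: Tumour-Surface Zonation and Spatial Statistics for Imaging-Based
    Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for imaging-based single-cell spatial
    transcriptomics of tumour tissue: per-cell marker positivity calling and
    cell typing, gene-density statistics with Welch tests, Benjamini-Hochberg
    correction and Cohen's d, a grid-graph signed distance field from the
    tumour surface (marker-rule mask, median/blur smoothing, border-following
    contour, multi-source shortest paths), distance-band stratification with
    centroid-linkage clustering of band expression profiles, spot-level
    top-quantile differential expression with hypergeometric
    over-representation maps and map correlation, and hot/cold tumour-cell
    contrasts. Includes a seeded synthetic-tissue generator emitting the same
    file dialects the readers consume, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
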