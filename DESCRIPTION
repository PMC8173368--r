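Package: stmia
Title: Integration of Spatial Transcriptomics and Single-Cell RNA-Seq by
    Multimodal Intersection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for integrating spatial transcriptomics (ST)
    spot-level UMI count data with single-cell RNA-seq: quality-control
    filtering, median-scaling log2 normalization, variable-gene selection,
    Ward hierarchical clustering, per-cluster differential expression with a
    bimodal (zero-inflated normal) likelihood-ratio test, multimodal
    intersection analysis (MIA) mapping cell types onto tissue regions via
    hypergeometric enrichment/depletion of marker-gene overlaps, gene-set
    average cell-cycle scoring with quiescent/proliferative classification,
    and monotone stage-trend gene calling. Includes a negative-binomial
    synthetic-data generator that plants regions, cell types, marker genes,
    cell-cycle phases and QC failures as known ground truth so every stage
    of the analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
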