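Package: scSupergroup
Title: Resolution-Optimized Super-Group Subclustering and Balanced Regulon
    Consensus for Droplet scRNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quality control and fine subclustering of droplet
    single-cell RNA-seq data, modelled on a single-cell atlas of the
    Drosophila larval lymph gland. Implements knee-point barcode selection
    from cumulative read curves, sequential per-library cell filters,
    exclusion of dissociation-induced stress genes by comparison with
    matched bulk RNA-seq, a clustering-resolution sweep that prunes weakly
    correlated subclusters and merges highly correlated ones into
    super-groups so as to maximize the number of differentially expressed
    genes, cell-cycle quartile scoring, and a balanced-resampling consensus
    that rescues transcription-factor regulon activity in small cell
    populations. A negative-binomial cohort simulator with planted
    subtypes, batch effects, ambient barcodes, stress programs and regulons
    supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    scran,
    mclust,
    jsonlite
biocViews: SingleCell, Transcriptomics, Clustering, QualityControl,
    GeneRegulation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
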