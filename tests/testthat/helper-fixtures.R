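# Small in-code fixtures used across test files.

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# A SingleCellExperiment from a plain matrix, with optional library labels
makeSce <- function(m, libs = NULL, timepoint = NULL, condition = NULL) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  cd$library <- if (is.null(libs)) rep("lib1", ncol(m)) else libs
  if (!is.null(timepoint)) cd$timepoint <- timepoint
  if (!is.null(condition)) cd$condition <- condition
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

# A small cohort reused by several files (cached per session)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateCohort(synthConfig(
        nCells = 600L, nGenes = 400L, nAmbientBarcodes = 150L,
        markerGenesPerSubtype = c(15L, 15L, 15L, 100L),
        stressGeneCount = 10L, seed = 42L))
    }
    cache
  }
})

realCells <- function(cohort) {
  colnames(cohort$sce)[!ambientFlag(cohort$truth)[colnames(cohort$sce)]]
}
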