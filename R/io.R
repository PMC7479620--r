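#' Write a cohort to Matrix Market + TSV files
#'
#' Writes `matrix.mtx` (genes x barcodes), `genes.tsv`, `barcodes.tsv`
#' and `cells_metadata.tsv` (barcode, library, timepoint, condition) to a
#' directory, the plain-text layout produced by droplet pipelines.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .counts(sce)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  meta <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  for (col in c("library", "timepoint", "condition")) {
    if (col %in% names(cd)) meta[[col]] <- as.character(cd[[col]])
  }
  utils::write.table(meta, file.path(dir, "cells_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and (optionally) `cells_metadata.tsv`.
#' @return a `SingleCellExperiment` with a sparse `counts` assay.
#' @export
readCohort <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cd <- NULL
  metaPath <- file.path(dir, "cells_metadata.tsv")
  if (file.exists(metaPath)) {
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    stopifnot(identical(meta$barcode, colnames(m)))
    cd <- S4Vectors::DataFrame(meta[, setdiff(names(meta), "barcode"),
                                    drop = FALSE],
                               row.names = meta$barcode)
  }
  if (is.null(cd)) {
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
  } else {
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m),
                                               colData = cd)
  }
}

#' Write / read a bulk gene-count table
#'
#' @param bulk a `data.frame` with columns `gene` and `count`.
#' @param path TSV path.
#' @return `writeBulkProfile` returns `path` invisibly;
#'   `readBulkProfile` returns the table.
#' @export
writeBulkProfile <- function(bulk, path) {
  stopifnot(all(c("gene", "count") %in% names(bulk)))
  utils::write.table(bulk[, c("gene", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBulkProfile
#' @export
readBulkProfile <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read simulator ground truth as JSON
#'
#' Serializes a [SyntheticTruth-class] so a simulated cohort written with
#' [writeCohort()] can be reloaded with its labels intact.  Requires the
#' \pkg{jsonlite} package.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON path.
#' @return `writeTruth` returns `path` invisibly; `readTruth` returns the
#'   reconstructed `SyntheticTruth`.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writeTruth requires the jsonlite package", call. = FALSE)
  }
  payload <- list(
    barcode = names(truth@subtype),
    subtype = unname(truth@subtype),
    library = unname(truth@library),
    coarseGroup = unname(truth@coarseGroup),
    ambient = unname(truth@ambient),
    stressGenes = truth@stressGenes,
    stressLogfc = truth@stressLogfc,
    markerMap = truth@markerMap,
    regulonTruth = truth@regulonTruth,
    regulonTargets = truth@regulonTargets,
    cyclingSubtypes = truth@cyclingSubtypes,
    ccGenes = truth@ccGenes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("readTruth requires the jsonlite package", call. = FALSE)
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(x) {
    x <- as.character(x)
    x[x == "NA"] <- NA_character_
    x
  }
  toList <- function(x) lapply(as.list(x), as.character)
  methods::new(
    "SyntheticTruth",
    subtype = stats::setNames(asChr(p$subtype), p$barcode),
    library = stats::setNames(as.character(p$library), p$barcode),
    coarseGroup = stats::setNames(asChr(p$coarseGroup), p$barcode),
    ambient = stats::setNames(as.logical(p$ambient), p$barcode),
    stressGenes = as.character(p$stressGenes),
    stressLogfc = as.numeric(p$stressLogfc),
    markerMap = toList(p$markerMap),
    regulonTruth = toList(p$regulonTruth),
    regulonTargets = toList(p$regulonTargets),
    cyclingSubtypes = as.character(p$cyclingSubtypes),
    ccGenes = as.character(p$ccGenes))
}
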