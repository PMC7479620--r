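#' Depth-normalize and log-transform UMI counts
#'
#' Scales every cell to a common total and log-transforms:
#' `value = log(pseudocount + count / cellTotal * targetTotal)`.  With the
#' default pseudocount of 1 this is the usual `log1p` of counts per ten
#' thousand and zeros map to zeros, so sparsity is preserved.  The
#' transform is invertible: the original counts are recovered from the
#' stored normalization metadata to within floating-point error.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay; every cell
#'   must have a positive total.
#' @param targetTotal common cell total after scaling (default 10000).
#' @param pseudocount offset inside the log (default 1).
#' @return `sce` with an added `logcounts` assay and the normalization
#'   parameters in `metadata(sce)$normalization`.
#' @export
normalizeCounts <- function(sce, targetTotal = 10000, pseudocount = 1) {
  counts <- .counts(sce)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)[1L]]
    stop(sprintf("cell '%s' has zero total count", bad), call. = FALSE)
  }
  if (pseudocount == 1 && is(counts, "CsparseMatrix")) {
    m <- counts
    m@x <- log1p(m@x / rep.int(totals, diff(m@p)) * targetTotal)
  } else {
    m <- log(pseudocount +
               sweep(as.matrix(counts), 2, totals, "/") * targetTotal)
  }
  SummarizedExperiment::assay(sce, "logcounts") <- m
  S4Vectors::metadata(sce)$normalization <-
    list(targetTotal = targetTotal, pseudocount = pseudocount,
         logBase = exp(1))
  sce
}

#' Dispersion-ranked variable genes
#'
#' Ranks genes by the dispersion (variance over mean) of their normalized
#' log-expression and returns the top `n`.  Genes with zero mean or zero
#' variance are ineligible; ties are broken by gene-identifier order so
#' the selection is deterministic.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay.
#' @param n number of genes to return (default 2000); when fewer genes
#'   are eligible, all of them are returned with a warning.
#' @return character vector of gene identifiers, most dispersed first.
#' @export
selectVariableGenes <- function(sce, n = 2000L) {
  lc <- .logcounts(sce)
  st <- .rowStats(lc)
  eligible <- st$mean > 0 & st$var > 0
  disp <- st$var[eligible] / st$mean[eligible]
  genes <- rownames(lc)[eligible]
  ord <- order(-disp, genes)
  if (n > length(genes)) {
    warning(sprintf("only %d genes with nonzero variance; returning all",
                    length(genes)), call. = FALSE)
    n <- length(genes)
  }
  genes[ord][seq_len(n)]
}
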