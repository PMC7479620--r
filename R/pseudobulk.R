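#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw UMI counts over the cells of each group and derives the
#' log1p-CPM transform used for inter-group correlation.  Raw sums are
#' conserved: summing over groups recovers the total counts of the
#' matrix.
#'
#' @param sce a `SingleCellExperiment` (or counts matrix).
#' @param labels group label per cell, either named by barcode or
#'   positionally aligned; every cell must be labeled.
#' @return a [PseudobulkProfile-class].
#' @export
pseudobulk <- function(sce, labels) {
  counts <- .counts(sce)
  labels <- .alignLabels(labels, colnames(counts), "group labels")
  groups <- sort(unique(labels))
  raw <- vapply(groups, function(g) {
    Matrix::rowSums(counts[, labels == g, drop = FALSE])
  }, numeric(nrow(counts)))
  raw <- matrix(raw, nrow = nrow(counts),
                dimnames = list(rownames(counts), groups))
  sizes <- vapply(groups, function(g) sum(labels == g), integer(1))
  if (any(sizes == 0L)) {
    stop("empty group in pseudobulk aggregation", call. = FALSE)
  }
  methods::new("PseudobulkProfile", rawSums = raw,
               logCPM = .logCpmOf(raw), sizes = sizes)
}

.logCpmOf <- function(raw) {
  tot <- colSums(raw)
  if (any(tot <= 0)) {
    stop("group with zero total counts", call. = FALSE)
  }
  log1p(sweep(raw, 2, tot, "/") * 1e6)
}

#' Pearson correlation between pseudo-bulk profiles
#'
#' Correlates the log1p-CPM profiles of all group pairs over a selected
#' gene list (typically the top variable genes).
#'
#' @param profiles a [PseudobulkProfile-class] with at least two groups.
#' @param genes gene identifiers to correlate over; must be present in
#'   the profile.
#' @return a symmetric correlation matrix with unit diagonal, labeled by
#'   group.
#' @export
correlationMatrix <- function(profiles, genes) {
  stopifnot(is(profiles, "PseudobulkProfile"))
  lcpm <- logCPM(profiles)
  if (ncol(lcpm) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  missing <- setdiff(genes, rownames(lcpm))
  if (length(missing) > 0L) {
    stop(sprintf("%d gene(s) absent from the profile, e.g. '%s'",
                 length(missing), missing[1L]), call. = FALSE)
  }
  sub <- lcpm[genes, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(sub)[which(sds == 0)[1L]]
    stop(sprintf("group '%s' has zero variance over the gene list", bad),
         call. = FALSE)
  }
  stats::cor(sub)
}
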