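#' Single-cell versus bulk fold-change table
#'
#' Dissociation into single cells induces a stress-response program absent
#' from matched bulk RNA-seq of the same tissue.  This table supports its
#' removal: the single-cell pseudo-bulk profile (per-gene column sums of
#' the UMI matrix) and the bulk count table are both scaled to counts per
#' million, and their ratio is computed with a pseudocount so genes absent
#' on one side get a finite ratio.  Genes missing from one side are
#' treated as zero counts there.
#'
#' @param sce a `SingleCellExperiment` (or counts matrix).
#' @param bulk a `data.frame` with columns `gene` and `count`, as from
#'   [makeBulkProfile()] or [readBulkProfile()].
#' @param pseudocount added to both CPM values before the ratio
#'   (default 1).
#' @param foldThreshold ratio at or beyond which a gene is flagged
#'   (default 10): `up` when `ratio >= foldThreshold`, `down` when
#'   `ratio <= 1/foldThreshold`, otherwise `pass`.
#' @return a `data.frame` with columns `gene`, `scCpm`, `bulkCpm`,
#'   `ratio`, `flag`, over the union of both gene universes.
#' @seealso [flagStressGenes()]
#' @export
foldChangeTable <- function(sce, bulk, pseudocount = 1,
                            foldThreshold = 10) {
  stopifnot(is.data.frame(bulk), all(c("gene", "count") %in% names(bulk)))
  counts <- .counts(sce)
  scSum <- Matrix::rowSums(counts)
  bulkSum <- stats::setNames(as.numeric(bulk$count), as.character(bulk$gene))
  if (length(intersect(names(scSum), names(bulkSum))) == 0L) {
    stop("single-cell and bulk gene universes do not intersect",
         call. = FALSE)
  }
  genes <- union(names(scSum), names(bulkSum))
  sc <- stats::setNames(numeric(length(genes)), genes)
  bk <- sc
  sc[names(scSum)] <- scSum
  bk[names(bulkSum)] <- bulkSum
  if (sum(sc) <= 0 || sum(bk) <= 0) {
    stop("zero total counts on one side", call. = FALSE)
  }
  scCpm <- sc / sum(sc) * 1e6
  bulkCpm <- bk / sum(bk) * 1e6
  ratio <- (scCpm + pseudocount) / (bulkCpm + pseudocount)
  tab <- data.frame(gene = genes, scCpm = as.numeric(scCpm),
                    bulkCpm = as.numeric(bulkCpm),
                    ratio = as.numeric(ratio),
                    flag = .stressFlag(ratio, foldThreshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "pseudocount") <- pseudocount
  attr(tab, "foldThreshold") <- foldThreshold
  tab
}

.stressFlag <- function(ratio, foldThreshold) {
  ifelse(ratio >= foldThreshold, "up",
         ifelse(ratio <= 1 / foldThreshold, "down", "pass"))
}

#' Flag and exclude stress-discordant genes
#'
#' Genes at least `foldThreshold`-fold up- or down-discordant between the
#' single-cell pseudo-bulk and the matched bulk profile are excluded from
#' downstream clustering as likely preparation artifacts.
#'
#' @param table a [foldChangeTable()].
#' @param foldThreshold fold-change cutoff (> 1; default 10).
#' @return a list with `excluded` (gene identifiers), `nUp`, `nDown`, and
#'   `table` (the input with flags recomputed at `foldThreshold`).
#' @export
#' @examples
#' tab <- data.frame(gene = c("a", "b", "c"), scCpm = 0, bulkCpm = 0,
#'                   ratio = c(20, 0.05, 2), flag = "pass")
#' flagStressGenes(tab)$excluded
flagStressGenes <- function(table, foldThreshold = 10) {
  stopifnot(is.data.frame(table), all(c("gene", "ratio") %in% names(table)))
  if (foldThreshold <= 1) {
    stop("foldThreshold must be greater than 1", call. = FALSE)
  }
  table$flag <- .stressFlag(table$ratio, foldThreshold)
  list(excluded = table$gene[table$flag != "pass"],
       nUp = sum(table$flag == "up"),
       nDown = sum(table$flag == "down"),
       table = table)
}
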