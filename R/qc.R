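#' Cumulative read-fraction curve over ranked barcodes
#'
#' Sorts barcodes by their read (or UMI) totals in decreasing order and
#' accumulates the fraction of all reads captured by the top-ranked
#' barcodes.  The resulting curve has a characteristic two-slope shape
#' when real cells and ambient barcodes coexist, and is the input of
#' [detectKnee()].
#'
#' @param reads named numeric vector of non-negative read counts per
#'   barcode (at least two barcodes, positive total).
#' @return a `data.frame` with columns `barcode`, `reads`, `rank` and
#'   `cumFraction`; `cumFraction` is non-decreasing and ends at 1.
#' @export
#' @examples
#' cumulativeCurve(c(A = 300, B = 100))
cumulativeCurve <- function(reads) {
  if (length(reads) < 2L) {
    stop("at least two barcodes are required", call. = FALSE)
  }
  if (any(reads < 0) || anyNA(reads)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  total <- sum(reads)
  if (total <= 0) {
    stop("total read count is zero", call. = FALSE)
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("barcode%06d", seq_along(reads))
  }
  ord <- order(reads, decreasing = TRUE)
  sorted <- reads[ord]
  data.frame(
    barcode = names(sorted),
    reads = as.numeric(sorted),
    rank = seq_along(sorted),
    cumFraction = cumsum(as.numeric(sorted)) / total,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Knee point of a cumulative barcode-rank curve
#'
#' Locates the rank at which the cumulative curve bends — the boundary
#' between real cells and ambient barcodes — as the point of maximal
#' perpendicular distance above the straight line joining the curve's
#' endpoints in (log10 rank, cumulative fraction) space.  The distance is
#' signed: the knee is where the curve bulges farthest above the chord
#' (the saturation bend), not where it dips below it early in the rank
#' order.  The read count of the barcode at that rank is returned as the
#' selection threshold: barcodes with at least that many reads are
#' considered cells.
#'
#' @param curve a curve from [cumulativeCurve()].
#' @return a list with `threshold` (reads at the knee rank), `rank` (the
#'   knee rank) and `distance` (the maximal perpendicular distance).
#' @export
detectKnee <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("reads", "rank", "cumFraction") %in% names(curve)))
  n <- nrow(curve)
  if (n < 3L) {
    stop("no knee: need at least three barcodes", call. = FALSE)
  }
  x <- log10(curve$rank)
  y <- curve$cumFraction
  dx <- x[n] - x[1L]
  dy <- y[n] - y[1L]
  len <- sqrt(dx^2 + dy^2)
  # signed distance above the chord: positive where the curve saturates
  d <- (dx * y - dy * x - (x[n] * y[1L] - y[n] * x[1L])) / len
  if (max(d) < 1e-12) {
    stop("no knee: curve is linear in (log10 rank, cumulative fraction)",
         call. = FALSE)
  }
  k <- which.max(d)
  list(threshold = curve$reads[k], rank = curve$rank[k], distance = d[k])
}

#' Per-cell quality-control thresholds
#'
#' @param minReads `"auto"` for per-library knee detection on the cell
#'   UMI totals, a single count applied to all libraries, or a named
#'   numeric vector with one explicit threshold per library (this is how
#'   per-library hand-picked values, e.g. 30,000 reads for a deep
#'   library, are reproduced).
#' @param geneLower,geneUpper inclusive bounds on detected genes per cell
#'   (defaults 400 and 5000).
#' @param umiSdMult cells with total UMI above
#'   `mean + umiSdMult * sd` (computed per library over cells surviving
#'   the gene filter) are removed as likely multiplets; default 2.
#' @param mitoMaxFraction maximal mitochondrial UMI fraction; default 0.10.
#' @param mitoGenes character vector of mitochondrial gene identifiers;
#'   when `NULL`, genes prefixed `mt:` are used.
#' @return a validated list of class `QcThresholds`.
#' @seealso [qcFilterCells()]
#' @export
qcThresholds <- function(minReads = "auto", geneLower = 400L,
                         geneUpper = 5000L, umiSdMult = 2,
                         mitoMaxFraction = 0.10, mitoGenes = NULL) {
  if (geneLower >= geneUpper) {
    stop("geneLower must be smaller than geneUpper", call. = FALSE)
  }
  if (mitoMaxFraction <= 0 || mitoMaxFraction >= 1) {
    stop("mitoMaxFraction must lie in (0, 1)", call. = FALSE)
  }
  if (!(identical(minReads, "auto") || is.numeric(minReads))) {
    stop("minReads must be \"auto\" or numeric", call. = FALSE)
  }
  structure(list(minReads = minReads, geneLower = as.integer(geneLower),
                 geneUpper = as.integer(geneUpper), umiSdMult = umiSdMult,
                 mitoMaxFraction = mitoMaxFraction, mitoGenes = mitoGenes),
            class = "QcThresholds")
}

#' Sequential per-cell quality filtering
#'
#' Applies, in order: (1) a per-library minimum-reads rule (knee-detected
#' from the library's cumulative UMI curve when `minReads = "auto"`),
#' (2) inclusive bounds on the number of detected genes, (3) removal of
#' cells whose UMI total exceeds `mean + umiSdMult * sd`, with mean and sd
#' computed per library over the cells surviving step 2, and (4) removal
#' of cells whose mitochondrial UMI fraction exceeds `mitoMaxFraction`.
#' Each barcode is removed at the first rule it fails, so the report
#' satisfies `nIn = nRetained + sum(removed)`.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay and a
#'   `library` column in its `colData`.
#' @param thresholds a [qcThresholds()].
#' @return a list with `sce` (the filtered object) and `report`
#'   (a [QcReport-class]).
#' @export
qcFilterCells <- function(sce, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "QcThresholds"))
  counts <- .counts(sce)
  if (is.null(colnames(counts))) {
    stop("cell barcodes (column names) are required", call. = FALSE)
  }
  lib <- as.character(SummarizedExperiment::colData(sce)$library)
  if (length(lib) == 0L || anyNA(lib)) {
    stop("colData(sce)$library is required for per-library filtering",
         call. = FALSE)
  }
  names(lib) <- colnames(counts)
  nIn <- ncol(counts)
  totals <- Matrix::colSums(counts)
  removed <- c(knee = 0L, genes = 0L, umi = 0L, mito = 0L)

  # step 1: minimum reads per cell, per library
  keep <- colnames(counts)
  mr <- thresholds$minReads
  thr <- vapply(unique(lib), function(l) {
    if (identical(mr, "auto")) {
      detectKnee(cumulativeCurve(totals[names(lib)[lib == l]]))$threshold
    } else if (length(mr) > 1L || !is.null(names(mr))) {
      if (!l %in% names(mr)) {
        stop(sprintf("no minReads entry for library '%s'", l),
             call. = FALSE)
      }
      as.numeric(mr[[l]])
    } else {
      as.numeric(mr)
    }
  }, numeric(1))
  keep <- keep[totals[keep] >= thr[lib[keep]]]
  removed["knee"] <- nIn - length(keep)
  .assertCellsLeft(keep, "minimum reads (knee)")

  # step 2: detected-gene bounds (inclusive)
  nGenes <- Matrix::colSums(counts[, keep, drop = FALSE] > 0)
  pass <- nGenes >= thresholds$geneLower & nGenes <= thresholds$geneUpper
  removed["genes"] <- sum(!pass)
  keep <- keep[pass]
  .assertCellsLeft(keep, "detected-gene bounds")

  # step 3: UMI outliers, mean/sd per library over step-2 survivors
  drop3 <- logical(length(keep))
  for (l in unique(lib[keep])) {
    inLib <- lib[keep] == l
    tot <- totals[keep][inLib]
    s <- stats::sd(tot)
    if (is.na(s)) s <- 0
    drop3[inLib] <- tot > mean(tot) + thresholds$umiSdMult * s
  }
  removed["umi"] <- sum(drop3)
  keep <- keep[!drop3]
  .assertCellsLeft(keep, "UMI outlier")

  # step 4: mitochondrial fraction
  mito <- thresholds$mitoGenes
  if (is.null(mito)) mito <- grep("^mt:", rownames(counts), value = TRUE)
  absent <- setdiff(mito, rownames(counts))
  if (length(absent) > 0L) {
    warning(sprintf("%d mitochondrial gene(s) absent from the matrix",
                    length(absent)), call. = FALSE)
    mito <- intersect(mito, rownames(counts))
  }
  if (length(mito) > 0L) {
    mitoFrac <- Matrix::colSums(counts[mito, keep, drop = FALSE]) /
      totals[keep]
    dropMito <- mitoFrac > thresholds$mitoMaxFraction
  } else {
    dropMito <- logical(length(keep))
  }
  removed["mito"] <- sum(dropMito)
  keep <- keep[!dropMito]
  .assertCellsLeft(keep, "mitochondrial fraction")

  report <- methods::new("QcReport", nIn = nIn, removed = removed,
                         nRetained = length(keep))
  list(sce = sce[, keep], report = report)
}

.assertCellsLeft <- function(keep, step) {
  if (length(keep) == 0L) {
    stop(sprintf("all cells removed at the %s step", step), call. = FALSE)
  }
  invisible(TRUE)
}
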