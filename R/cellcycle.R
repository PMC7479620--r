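#' Cell-cycle phase gene sets
#'
#' Default sets follow the Drosophila cell-cycle regulators commonly used
#' for lymph-gland hemocytes: Cdk1/CycD/CycE for G1, stg/CycA/CycB for
#' G2, and polo/aurB/Det for M phase.  Phase lists must be non-empty and
#' pairwise disjoint.  Gene identifiers are matched case-sensitively.
#'
#' @param g1,g2,m character vectors of phase genes.
#' @return a validated list of class `PhaseGeneSets`.
#' @export
phaseGeneSets <- function(g1 = c("Cdk1", "CycD", "CycE"),
                          g2 = c("stg", "CycA", "CycB"),
                          m = c("polo", "aurB", "Det")) {
  sets <- list(g1 = as.character(g1), g2 = as.character(g2),
               m = as.character(m))
  if (any(lengths(sets) == 0L)) {
    stop("every phase gene list must be non-empty", call. = FALSE)
  }
  if (length(unlist(sets)) != length(unique(unlist(sets)))) {
    stop("phase gene lists must be disjoint", call. = FALSE)
  }
  structure(sets, class = "PhaseGeneSets")
}

#' Per-cell cell-cycle phase scores
#'
#' Each phase score is the mean normalized log-expression of that phase's
#' genes in the cell; the total score is their sum (G1 + G2 + M).  Phase
#' genes absent from the matrix are dropped with a warning; a phase with
#' no present genes is an error.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay.
#' @param sets a [phaseGeneSets()].
#' @return a `data.frame` with columns `barcode`, `g1`, `g2`, `m`,
#'   `total`.
#' @export
phaseScores <- function(sce, sets = phaseGeneSets()) {
  stopifnot(inherits(sets, "PhaseGeneSets"))
  lc <- .logcounts(sce)
  scores <- lapply(names(sets), function(ph) {
    present <- intersect(sets[[ph]], rownames(lc))
    absent <- setdiff(sets[[ph]], rownames(lc))
    if (length(present) == 0L) {
      stop(sprintf("no %s-phase genes present in the matrix",
                   toupper(ph)), call. = FALSE)
    }
    if (length(absent) > 0L) {
      warning(sprintf("%s-phase gene(s) absent: %s", toupper(ph),
                      paste(absent, collapse = ", ")), call. = FALSE)
    }
    Matrix::colMeans(lc[present, , drop = FALSE])
  })
  names(scores) <- names(sets)
  data.frame(barcode = colnames(lc), g1 = as.numeric(scores$g1),
             g2 = as.numeric(scores$g2), m = as.numeric(scores$m),
             total = as.numeric(scores$g1 + scores$g2 + scores$m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Retain cells above a cell-cycle score quantile
#'
#' Computes the empirical quantile (linear interpolation, type 7) of the
#' total cell-cycle score and retains cells at or above it — the
#' complement of removing cells below the third quartile.  The threshold
#' is data-dependent and reported alongside the retained set.
#'
#' @param scores a table from [phaseScores()].
#' @param quantile probability of the retention threshold (default
#'   0.75).
#' @return a list with `retained` (barcodes), `threshold`, and
#'   `quantile`.
#' @export
cyclingFilter <- function(scores, quantile = 0.75) {
  stopifnot(is.data.frame(scores),
            all(c("barcode", "total") %in% names(scores)))
  if (nrow(scores) < 4L) {
    stop("at least four cells are required", call. = FALSE)
  }
  if (length(unique(scores$total)) == 1L) {
    warning("all total scores identical; retaining every cell",
            call. = FALSE)
    return(list(retained = scores$barcode,
                threshold = scores$total[1L], quantile = quantile))
  }
  thr <- stats::quantile(scores$total, probs = quantile, type = 7,
                         names = FALSE)
  list(retained = scores$barcode[scores$total >= thr], threshold = thr,
       quantile = quantile)
}

#' Subclusters enriched for retained (cycling) cells
#'
#' Lists the subclusters in which strictly more than `minFrac` of the
#' original population survives the cell-cycle filter — the
#' proliferative subclusters.
#'
#' @param retained barcodes retained by [cyclingFilter()].
#' @param labels subcluster label per cell (must cover the retained
#'   cells).
#' @param minFrac retention fraction threshold (default 0.25; strict).
#' @return character vector of proliferative subcluster labels.
#' @export
proliferativeSubclusters <- function(retained, labels, minFrac = 0.25) {
  if (is.null(names(labels))) {
    stop("labels must be named by cell barcode", call. = FALSE)
  }
  miss <- setdiff(retained, names(labels))
  if (length(miss) > 0L) {
    stop(sprintf("labels missing for %d retained cell(s)", length(miss)),
         call. = FALSE)
  }
  groups <- sort(unique(as.character(labels)))
  frac <- vapply(groups, function(g) {
    size <- sum(labels == g)
    if (size == 0L) stop("empty subcluster", call. = FALSE)
    sum(retained %in% names(labels)[labels == g]) / size
  }, numeric(1))
  groups[frac > minFrac]
}
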