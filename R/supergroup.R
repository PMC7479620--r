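#' Iteratively exclude weakly correlated subclusters
#'
#' While the minimum off-diagonal Pearson correlation is below `rMin` and
#' more than two groups remain, the group with the smallest mean
#' off-diagonal correlation is removed (ties: smaller size, then label
#' order) and the criterion is recomputed on the remaining submatrix.
#' With exactly two groups no removal is possible; if their correlation
#' is still below the floor, both are retained with a warning.
#'
#' @param corr a labeled correlation matrix from [correlationMatrix()].
#' @param sizes named group sizes (used only for tie-breaking).
#' @param rMin correlation floor (default 0.90).
#' @return a list with `retained` (labels), `excluded` (labels in removal
#'   order) and `corr` (the final submatrix).
#' @export
excludeUncorrelated <- function(corr, sizes, rMin = 0.90) {
  stopifnot(is.matrix(corr), identical(rownames(corr), colnames(corr)))
  if (ncol(corr) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  sizes <- sizes[colnames(corr)]
  excluded <- character(0)
  while (ncol(corr) > 2L && min(.offdiag(corr)) < rMin) {
    meanOff <- (rowSums(corr) - 1) / (ncol(corr) - 1)
    ord <- order(meanOff, sizes[colnames(corr)], colnames(corr))
    worst <- colnames(corr)[ord[1L]]
    excluded <- c(excluded, worst)
    keep <- setdiff(colnames(corr), worst)
    corr <- corr[keep, keep, drop = FALSE]
  }
  if (ncol(corr) == 2L && min(.offdiag(corr)) < rMin) {
    warning(sprintf(paste0("two groups remain with correlation %.3f < ",
                           "%.2f; both retained"),
                    min(.offdiag(corr)), rMin), call. = FALSE)
  }
  list(retained = colnames(corr), excluded = excluded, corr = corr)
}

#' Agglomerate highly correlated subclusters into super-groups
#'
#' While the maximum off-diagonal Pearson correlation between current
#' group profiles is at least `rMerge`, the most-correlated pair is
#' merged (ties: first pair in label order) and its pseudo-bulk profile
#' is recomputed from the pooled cell counts — not by averaging the two
#' profiles — before correlations are recomputed.  The result is a
#' partition coarsening whose final profiles all correlate below
#' `rMerge`.
#'
#' @param sce a `SingleCellExperiment` (or counts matrix).
#' @param labels fine cluster label per cell.
#' @param genes gene list for the correlations (typically variable
#'   genes).
#' @param rMerge merge threshold (default 0.95).
#' @return a list with `map` (named character, fine cluster ->
#'   super-group; merged super-groups are named by joining their members
#'   with `+`), `corr` (final correlation matrix, or `NULL` for a single
#'   group), `profiles` (final [PseudobulkProfile-class]) and `history`
#'   (list of merge steps, each the two member sets that were pooled, in
#'   order).
#' @export
mergeSupergroups <- function(sce, labels, genes, rMerge = 0.95) {
  counts <- .counts(sce)
  labels <- .alignLabels(labels, colnames(counts), "cluster labels")
  pb <- pseudobulk(counts, labels)
  raw <- rawSums(pb)
  sizes <- groupSizes(pb)
  members <- stats::setNames(as.list(colnames(raw)), colnames(raw))

  if (ncol(raw) == 1L) {
    map <- stats::setNames(colnames(raw), colnames(raw))
    return(list(map = map, corr = NULL, profiles = pb,
                history = list()))
  }

  history <- list()
  repeat {
    lcpm <- .logCpmOf(raw)[genes, , drop = FALSE]
    corr <- stats::cor(lcpm)
    if (ncol(corr) == 1L) break
    off <- corr
    diag(off) <- -Inf
    mx <- max(off)
    if (mx < rMerge) break
    # first maximal pair in label order
    labs <- colnames(corr)
    ordIdx <- order(labs)
    pair <- NULL
    for (a in seq_along(ordIdx)) {
      for (b in seq_along(ordIdx)) {
        if (b <= a) next
        i <- ordIdx[a]; j <- ordIdx[b]
        if (off[i, j] >= mx - 1e-12) { pair <- c(i, j); break }
      }
      if (!is.null(pair)) break
    }
    i <- pair[1L]; j <- pair[2L]
    history[[length(history) + 1L]] <-
      list(a = sort(unlist(members[[labs[i]]])),
           b = sort(unlist(members[[labs[j]]])))
    mem <- sort(unique(c(members[[labs[i]]], members[[labs[j]]])))
    newName <- paste(mem, collapse = "+")
    merged <- raw[, i] + raw[, j]
    keep <- setdiff(seq_len(ncol(raw)), c(i, j))
    newSizes <- c(sizes[keep], sum(sizes[c(i, j)]))
    raw <- cbind(raw[, keep, drop = FALSE], merged)
    colnames(raw)[ncol(raw)] <- newName
    sizes <- stats::setNames(newSizes, colnames(raw))
    members <- c(members[labs[keep]], stats::setNames(list(mem), newName))
    if (ncol(raw) == 1L) break
  }

  map <- character(0)
  for (sg in names(members)) {
    map[members[[sg]]] <- sg
  }
  finalCorr <- if (ncol(raw) >= 2L) {
    stats::cor(.logCpmOf(raw)[genes, , drop = FALSE])
  } else NULL
  finalPb <- methods::new("PseudobulkProfile", rawSums = raw,
                          logCPM = .logCpmOf(raw),
                          sizes = stats::setNames(as.integer(sizes),
                                                  colnames(raw)))
  list(map = map[sort(names(map))], corr = finalCorr, profiles = finalPb,
       history = history)
}

#' Flag subclusters dominated by a single library
#'
#' A subcluster in which more than `frac` of the cells originate from one
#' sequencing library is likely an experimental artifact.  The comparison
#' is strict, so an exact 50/50 split over two libraries is not flagged
#' at the default `frac = 0.5`.
#'
#' @param labels subcluster label per cell.
#' @param libraries library label per cell (same cells).
#' @param frac maximal tolerated single-library share (default 0.5).
#' @return character vector of flagged subcluster labels.
#' @export
flagLibraryBiased <- function(labels, libraries, frac = 0.5) {
  cells <- names(labels)
  if (is.null(cells)) cells <- as.character(seq_along(labels))
  labels <- .alignLabels(labels, cells, "cluster labels")
  libraries <- .alignLabels(libraries, cells, "library labels")
  groups <- sort(unique(labels))
  flagged <- vapply(groups, function(g) {
    inG <- labels == g
    if (sum(inG) == 0L) stop("empty group", call. = FALSE)
    max(table(libraries[inG])) / sum(inG) > frac
  }, logical(1))
  groups[flagged]
}
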