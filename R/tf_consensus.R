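#' Expression filter for regulon-activity analysis
#'
#' With `N` cells, keeps genes whose total UMI count exceeds
#' `multiplier * (fraction * N)` and that are detected (count > 0) in at
#' least `fraction * N` cells.  Both thresholds are reported as real
#' numbers without rounding before comparison; e.g. 348 cells at the
#' default 3\% give a UMI threshold of 31.32 and a detection criterion
#' of 10.44 cells.
#'
#' @param sce a `SingleCellExperiment` (or counts matrix).
#' @param fraction cell fraction defining both thresholds, in (0, 1);
#'   default 0.03.
#' @param multiplier factor on the UMI threshold; default 3.
#' @return a list with `genes` (kept identifiers), `umiThreshold` and
#'   `minCells`.
#' @export
activityGeneFilter <- function(sce, fraction = 0.03, multiplier = 3) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  counts <- .counts(sce)
  if (ncol(counts) == 0L) stop("empty matrix", call. = FALSE)
  n <- ncol(counts)
  minCells <- fraction * n
  umiThreshold <- multiplier * minCells
  tot <- Matrix::rowSums(counts)
  det <- Matrix::rowSums(counts > 0)
  keep <- tot > umiThreshold & det >= minCells
  list(genes = rownames(counts)[keep], umiThreshold = umiThreshold,
       minCells = minCells)
}

#' Regulon definitions from a TF-target table
#'
#' @param x a `data.frame` with columns `tf` and `target`, or a path to
#'   a TSV with those columns.
#' @param minTargets regulons with fewer targets are dropped with a
#'   warning (default 5).
#' @return a named list, TF -> character vector of targets.
#' @export
readRegulons <- function(x, minTargets = 5L) {
  if (is.character(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("tf", "target") %in% names(x)))
  regs <- split(as.character(x$target), as.character(x$tf))
  regs <- lapply(regs, unique)
  self <- vapply(names(regs), function(tf) tf %in% regs[[tf]], logical(1))
  if (any(self)) {
    stop("a transcription factor cannot be its own target", call. = FALSE)
  }
  small <- lengths(regs) < minTargets
  if (any(small)) {
    warning(sprintf("dropping %d regulon(s) with fewer than %d targets",
                    sum(small), minTargets), call. = FALSE)
    regs <- regs[!small]
  }
  regs
}

#' Configuration of the balanced-resampling consensus
#'
#' @param trials number of resampling trials (default 100).
#' @param sampleFraction per-subcluster sample size as a fraction of the
#'   smallest subcluster (default 2/3; the draw uses
#'   `floor(sampleFraction * min size)` cells from every subcluster).
#' @param minHits trials in which a TF must be called active to enter
#'   the consensus (default 25).
#' @param geneFilterFraction,geneFilterMultiplier parameters of the
#'   per-trial [activityGeneFilter()] (defaults 0.03 and 3).
#' @param minorGroupFraction minimum group-by-stage cell share retained
#'   by [groupProfiles()] (default 0.001).
#' @param seed master seed; per-trial seeds are derived from it.
#' @return a validated list of class `ConsensusConfig`.
#' @export
consensusConfig <- function(trials = 100L, sampleFraction = 2 / 3,
                            minHits = 25L, geneFilterFraction = 0.03,
                            geneFilterMultiplier = 3,
                            minorGroupFraction = 0.001, seed = 1L) {
  if (sampleFraction <= 0 || sampleFraction > 1) {
    stop("sampleFraction must lie in (0, 1]", call. = FALSE)
  }
  if (minHits > trials) {
    stop("minHits cannot exceed trials", call. = FALSE)
  }
  structure(list(trials = as.integer(trials),
                 sampleFraction = sampleFraction,
                 minHits = as.integer(minHits),
                 geneFilterFraction = geneFilterFraction,
                 geneFilterMultiplier = geneFilterMultiplier,
                 minorGroupFraction = minorGroupFraction,
                 seed = as.integer(seed)),
            class = "ConsensusConfig")
}

#' Balanced per-subcluster cell sample
#'
#' Draws `k = floor(sampleFraction * smallest subcluster size)` cells
#' without replacement from every subcluster, so each subcluster
#' contributes equally regardless of its population size.
#'
#' @param labels subcluster label per cell, named by barcode.
#' @param sampleFraction fraction of the smallest subcluster (e.g. 2/3
#'   of a 63-cell subcluster gives k = 42).
#' @param seed integer seed; the draw is reproducible.
#' @return character vector of sampled barcodes with attribute `k`.
#' @export
balancedSample <- function(labels, sampleFraction, seed) {
  if (is.null(names(labels))) {
    stop("labels must be named by cell barcode", call. = FALSE)
  }
  labels <- stats::setNames(as.character(labels), names(labels))
  sizes <- table(labels)
  k <- floor(sampleFraction * min(sizes))
  if (k < 1L) {
    stop("smallest subcluster too small for fraction", call. = FALSE)
  }
  cells <- .withSeed(seed, {
    unlist(lapply(sort(unique(labels)), function(g) {
      sample(names(labels)[labels == g], k)
    }), use.names = FALSE)
  })
  attr(cells, "k") <- as.integer(k)
  cells
}

#' Rank-sum regulon-activity caller
#'
#' The per-trial activity call behind [runConsensus()].  On the given
#' cell subset it first applies [activityGeneFilter()]; regulons whose
#' targets all fail the filter are skipped.  Each surviving TF is scored
#' per cell as the mean normalized log-expression of its filtered
#' targets, and called active if some subcluster's score distribution
#' exceeds all other sampled cells by a one-sided rank-sum test
#' (Benjamini-Hochberg `q < qMax` over all TF-by-subcluster tests) with
#' a positive mean difference.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay.
#' @param cells barcodes of the (sampled) cells to analyze.
#' @param labels subcluster label per cell, named by barcode.
#' @param regulons named list, TF -> target genes.
#' @param qMax BH significance threshold (default 0.05).
#' @param geneFilterFraction,geneFilterMultiplier per-call
#'   [activityGeneFilter()] parameters.
#' @return character vector of active TFs.
#' @export
referenceCaller <- function(sce, cells, labels, regulons, qMax = 0.05,
                            geneFilterFraction = 0.03,
                            geneFilterMultiplier = 3) {
  lc <- .logcounts(sce)
  stopifnot(all(cells %in% colnames(lc)))
  labels <- .alignLabels(labels, cells, "subcluster labels")
  filt <- activityGeneFilter(.counts(sce)[, cells, drop = FALSE],
                             fraction = geneFilterFraction,
                             multiplier = geneFilterMultiplier)
  sub <- lc[, cells, drop = FALSE]
  groups <- sort(unique(labels))
  tests <- list()
  for (tf in names(regulons)) {
    targets <- intersect(regulons[[tf]], filt$genes)
    if (length(targets) == 0L) {
      warning(sprintf("regulon '%s' empty after gene filtering; skipped",
                      tf), call. = FALSE)
      next
    }
    score <- Matrix::colMeans(sub[targets, , drop = FALSE])
    for (g in groups) {
      inG <- labels == g
      if (!any(inG) || all(inG)) next
      tests[[length(tests) + 1L]] <- list(
        tf = tf,
        p = .ranksumGreater(score[inG], score[!inG]),
        diff = mean(score[inG]) - mean(score[!inG]))
    }
  }
  if (length(tests) == 0L) return(character(0))
  p <- vapply(tests, function(t) t$p, numeric(1))
  q <- bhAdjust(p)
  active <- vapply(tests, function(t) t$tf, character(1))[
    q < qMax & vapply(tests, function(t) t$diff, numeric(1)) > 0]
  sort(unique(active))
}

#' Balanced-resampling consensus of transcription-factor activity
#'
#' Activity calls on full droplet datasets under-detect regulons that
#' are only active in small subclusters, because population size feeds
#' into the expression filters and test power.  This consensus corrects
#' the bias: in each of `trials` trials an equal number of cells is
#' drawn from every subcluster ([balancedSample()], seeded from the
#' master seed and the trial index), the caller is run on that balanced
#' subset, and active TFs are tallied; TFs called in at least `minHits`
#' trials form the consensus set.
#'
#' @param sce a `SingleCellExperiment` with `counts` (a `logcounts`
#'   assay is added if missing).
#' @param labels subcluster label per cell, named by barcode.
#' @param regulons named list, TF -> target genes.
#' @param config a [consensusConfig()].
#' @param caller the per-trial activity caller; defaults to
#'   [referenceCaller()].  Any `function(sce, cells, labels, regulons,
#'   ...)` returning a character vector of TFs may be plugged in.
#' @return a [ConsensusResult-class].  A trial in which the caller
#'   errors is recorded as failed; more than 10\% failed trials aborts.
#' @export
runConsensus <- function(sce, labels, regulons,
                         config = consensusConfig(),
                         caller = referenceCaller) {
  stopifnot(inherits(config, "ConsensusConfig"), is.function(caller))
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    sce <- normalizeCounts(sce)
  }
  labels <- .alignLabels(labels, colnames(sce), "subcluster labels")
  trialSeeds <- .withSeed(config$seed,
                          sample.int(.Machine$integer.max,
                                     config$trials))
  hits <- stats::setNames(integer(length(regulons)), names(regulons))
  samples <- vector("list", config$trials)
  failed <- 0L
  for (t in seq_len(config$trials)) {
    cells <- balancedSample(labels, config$sampleFraction, trialSeeds[t])
    samples[[t]] <- cells
    active <- tryCatch(
      suppressWarnings(
        caller(sce, cells, labels[cells], regulons,
               geneFilterFraction = config$geneFilterFraction,
               geneFilterMultiplier = config$geneFilterMultiplier)),
      error = function(e) NULL)
    if (is.null(active)) {
      failed <- failed + 1L
      if (failed > 0.1 * config$trials) {
        stop("more than 10% of consensus trials failed", call. = FALSE)
      }
      next
    }
    known <- intersect(active, names(hits))
    hits[known] <- hits[known] + 1L
  }
  methods::new("ConsensusResult", hits = hits,
               trials = config$trials, minHits = config$minHits,
               consensus = names(hits)[hits >= config$minHits],
               trialSamples = samples, failedTrials = failed)
}

#' Scaled pseudo-bulk profiles per group and stage
#'
#' Drops group-by-stage combinations holding fewer than
#' `minorGroupFraction` of all cells (0.1\% of a ~19,000-cell dataset is
#' ~19 cells), z-scores each gene's normalized log-expression across the
#' remaining cells, and averages the z-scores per combination.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay.
#' @param labels group label per cell.
#' @param timepoints stage label per cell.
#' @param minorGroupFraction minimum cell share of a retained
#'   combination (default 0.001).
#' @return a genes-by-combinations matrix (columns `group.stage`), with
#'   attributes `cellThreshold` and `dropped`.
#' @export
groupProfiles <- function(sce, labels, timepoints,
                          minorGroupFraction = 0.001) {
  lc <- .logcounts(sce)
  cells <- colnames(lc)
  labels <- .alignLabels(labels, cells, "group labels")
  timepoints <- .alignLabels(timepoints, cells, "stage labels")
  combo <- paste(labels, timepoints, sep = ".")
  threshold <- minorGroupFraction * length(cells)
  sizes <- table(combo)
  keepCombos <- names(sizes)[sizes >= threshold]
  dropped <- setdiff(names(sizes), keepCombos)
  if (length(keepCombos) == 0L) {
    stop("all group-stage combinations fall below the cell threshold",
         call. = FALSE)
  }
  keep <- combo %in% keepCombos
  X <- as.matrix(lc[, keep, drop = FALSE])
  mu <- rowMeans(X)
  sd <- apply(X, 1L, stats::sd)
  Z <- (X - mu) / ifelse(sd > 0, sd, 1)
  Z[sd == 0, ] <- 0
  out <- vapply(keepCombos, function(cb) {
    rowMeans(Z[, combo[keep] == cb, drop = FALSE])
  }, numeric(nrow(Z)))
  out <- matrix(out, nrow = nrow(Z),
                dimnames = list(rownames(lc), keepCombos))
  attr(out, "cellThreshold") <- threshold
  attr(out, "dropped") <- dropped
  out
}
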