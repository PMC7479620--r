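#' Resolution sweep with correlation pruning and super-group merging
#'
#' For every resolution in `resGrid`: cluster the cells with `backend`,
#' aggregate the fine clusters to pseudo-bulk, correlate them over the
#' variable genes (selected once on the full input so scales are
#' comparable across the sweep), prune weakly correlated clusters with
#' [excludeUncorrelated()], merge highly correlated ones with
#' [mergeSupergroups()], and count the differentially expressed genes
#' among the resulting super-groups with [degCount()].  The solution with
#' the maximal DEG count wins; ties go to the lowest resolution.  A sweep
#' in which the backend never finds more than one cluster returns that
#' trivial solution (DEG count 0) with a warning.
#'
#' @param sce a `SingleCellExperiment`; a `logcounts` assay is added with
#'   [normalizeCounts()] if missing.  Cells should already be
#'   quality-filtered and stress genes excluded.
#' @param backend a cluster backend: `function(sce, resolution, seed)`
#'   returning one label per cell, deterministic given `seed`.  See
#'   [plantedPartitionBackend()] and [snnLouvainBackend()].
#' @param resGrid resolutions to sweep (default 0.1 to 3.0 in steps
#'   of 0.1).
#' @param seed integer seed forwarded to the backend.
#' @param hvgN number of variable genes for the correlations
#'   (default 2000, capped at the eligible genes).
#' @param rExclude correlation floor for pruning (default 0.90).
#' @param rMerge correlation threshold for merging (default 0.95).
#' @param qMax,lfcMin DEG significance thresholds passed to
#'   [degCount()].
#' @return a [SupergroupSolution-class].
#' @export
optimizeResolution <- function(sce, backend,
                               resGrid = seq(0.1, 3.0, by = 0.1),
                               seed = 1L, hvgN = 2000L,
                               rExclude = 0.90, rMerge = 0.95,
                               qMax = 0.05, lfcMin = 0.25) {
  stopifnot(is.function(backend), length(resGrid) >= 1L)
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    sce <- normalizeCounts(sce)
  }
  genes <- suppressWarnings(selectVariableGenes(sce, hvgN))
  cells <- colnames(sce)

  best <- NULL
  bestKey <- c(-Inf, Inf)  # (degCount, -resolution) preference
  trace <- data.frame(resolution = numeric(0), nClusters = integer(0),
                      nSupergroups = integer(0), degCount = integer(0))

  for (res in resGrid) {
    sol <- tryCatch(
      .sweepOneResolution(sce, backend, res, seed, genes, rExclude,
                          rMerge, qMax, lfcMin),
      error = function(e) NULL)
    if (is.null(sol)) {
      trace <- rbind(trace, data.frame(resolution = res,
                                       nClusters = NA_integer_,
                                       nSupergroups = NA_integer_,
                                       degCount = NA_integer_))
      next
    }
    trace <- rbind(trace, data.frame(resolution = res,
                                     nClusters = sol$nClusters,
                                     nSupergroups = sol$nSupergroups,
                                     degCount = sol$degCount))
    if (sol$degCount > bestKey[1L] ||
        (sol$degCount == bestKey[1L] && res < -bestKey[2L])) {
      bestKey <- c(sol$degCount, -res)
      best <- c(sol, list(resolution = res))
    }
  }
  if (is.null(best)) {
    stop("every resolution in the sweep failed", call. = FALSE)
  }
  if (all(stats::na.omit(trace$nClusters) == 1L)) {
    warning("backend returned a single cluster at every resolution",
            call. = FALSE)
  }
  methods::new("SupergroupSolution",
               resolution = best$resolution,
               fineLabels = best$fineLabels,
               excludedClusters = best$excluded,
               supergroupMap = best$map,
               degCount = as.integer(best$degCount),
               trace = trace)
}

.sweepOneResolution <- function(sce, backend, res, seed, genes, rExclude,
                                rMerge, qMax, lfcMin) {
  cells <- colnames(sce)
  labels <- .alignLabels(backend(sce, res, seed), cells, "backend labels")
  nClusters <- length(unique(labels))
  if (nClusters == 1L) {
    lab <- unique(labels)
    return(list(fineLabels = labels, excluded = character(0),
                map = stats::setNames(lab, lab), degCount = 0L,
                nClusters = 1L, nSupergroups = 1L))
  }
  pb <- pseudobulk(sce, labels)
  corr <- correlationMatrix(pb, genes)
  exc <- excludeUncorrelated(corr, groupSizes(pb), rMin = rExclude)
  keepCells <- cells[labels %in% exc$retained]
  merged <- mergeSupergroups(sce[, keepCells], labels[keepCells], genes,
                             rMerge = rMerge)
  superLabels <- merged$map[labels[keepCells]]
  names(superLabels) <- keepCells
  nSg <- length(unique(merged$map))
  dc <- if (nSg >= 2L) {
    suppressWarnings(degCount(sce[, keepCells], superLabels,
                              qMax = qMax, lfcMin = lfcMin)$count)
  } else 0L
  list(fineLabels = labels, excluded = exc$excluded, map = merged$map,
       degCount = dc, nClusters = nClusters, nSupergroups = nSg)
}

#' Planted-partition cluster backend
#'
#' A deterministic stand-in for graph-based community detection in which
#' the resolution parameter controls the granularity of a known label
#' hierarchy: below `coarseAt` all cells form one cluster, from
#' `coarseAt` the coarse labels are returned, from `fineAt` the fine
#' labels, and from `splitAt` each fine cluster is split into two random
#' (seeded) halves.  Useful for exercising the resolution sweep against
#' a generator's ground truth.
#'
#' @param fine named character, fine label per cell.
#' @param coarse optional named character, coarse label per cell
#'   (defaults to `fine`).
#' @param coarseAt,fineAt,splitAt resolution breakpoints.
#' @return a backend `function(sce, resolution, seed)`.
#' @export
plantedPartitionBackend <- function(fine, coarse = NULL, coarseAt = 0.3,
                                    fineAt = 0.8, splitAt = 2.0) {
  stopifnot(!is.null(names(fine)))
  if (is.null(coarse)) coarse <- fine
  force(coarseAt); force(fineAt); force(splitAt)
  function(sce, resolution, seed) {
    cells <- colnames(.counts(sce))
    if (resolution < coarseAt) {
      return(stats::setNames(rep("all", length(cells)), cells))
    }
    if (resolution < fineAt) {
      return(coarse[cells])
    }
    labs <- fine[cells]
    if (resolution < splitAt) {
      return(labs)
    }
    .withSeed(seed, {
      for (g in unique(labs)) {
        idx <- which(labs == g)
        half <- sample(idx, floor(length(idx) / 2))
        labs[half] <- paste0(g, ".a")
        labs[setdiff(idx, half)] <- paste0(g, ".b")
      }
      labs
    })
  }
}

#' Louvain community-detection backend on a shared-neighbor graph
#'
#' Builds a shared-nearest-neighbor graph on the variable-gene
#' log-expression (via \pkg{scran}) and partitions it with Louvain
#' modularity optimization at the given resolution (via \pkg{igraph}).
#'
#' @param k neighbors for the SNN graph (default 10).
#' @param d principal components used by the graph construction
#'   (default 20).
#' @param hvgN variable genes used (default 2000).
#' @return a backend `function(sce, resolution, seed)`.
#' @export
snnLouvainBackend <- function(k = 10L, d = 20L, hvgN = 2000L) {
  force(k); force(d); force(hvgN)
  function(sce, resolution, seed) {
    if (!requireNamespace("scran", quietly = TRUE) ||
        !requireNamespace("igraph", quietly = TRUE)) {
      stop("snnLouvainBackend requires the scran and igraph packages",
           call. = FALSE)
    }
    lc <- .logcounts(sce)
    genes <- suppressWarnings(selectVariableGenes(sce, hvgN))
    g <- scran::buildSNNGraph(lc[genes, , drop = FALSE], k = k,
                              d = min(d, length(genes) - 1L,
                                      ncol(lc) - 1L))
    mem <- .withSeed(seed,
                     igraph::cluster_louvain(g,
                                             resolution = resolution)$membership)
    stats::setNames(paste0("c", mem), colnames(lc))
  }
}
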