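#' Configuration for the negative-binomial cohort simulator
#'
#' Builds and validates the parameter set consumed by [simulateCohort()].
#' The defaults describe a desk-scale droplet cohort with the structure the
#' downstream stages assume: six planted subtypes forming four coarse
#' groups — two near-duplicate pairs whose pseudo-bulk profiles correlate
#' above the merge threshold, one ordinary singleton, and one
#' low-correlation "noise" subtype carrying a large private program —
#' library batch effects, a mitochondrial gene block, ambient low-count
#' barcodes, a dissociation-stress program present only in the single-cell
#' counts, a cycling subtype with an elevated cell-cycle program, and
#' optional regulons planted as near-binary target programs.
#'
#' @param nCells number of real cells.
#' @param nGenes number of genes.
#' @param nSubtypes number of planted subtypes.
#' @param subtypeProportions probability vector over subtypes
#'   (must sum to 1).
#' @param supergroupMap integer vector mapping each subtype to its coarse
#'   group; subtypes sharing a coarse group are near-duplicates that share
#'   that group's marker program and differ only in `dupMarkerCount`
#'   private genes.
#' @param nLibraries number of sequencing libraries; cells are assigned
#'   uniformly at random.
#' @param batchLogfcSd standard deviation (natural-log scale) of
#'   per-library per-gene batch effects.
#' @param markerGenesPerSubtype marker-program size per coarse group;
#'   scalar or one value per coarse group.  A large value (relative to
#'   `nGenes`) turns a group into a low-correlation outlier.
#' @param markerLogfc natural-log fold change of coarse-group markers.
#' @param dupMarkerCount number of private marker genes distinguishing
#'   each member of a near-duplicate pair.
#' @param dupLogfc natural-log fold change of the private markers.
#' @param nbDispersion shared negative-binomial dispersion (> 0); variance
#'   is `mu + dispersion * mu^2`.
#' @param meanDepth expected UMIs per cell before depth variation.
#' @param depthLogsd lognormal sd of per-cell depth factors.
#' @param baseLogSd lognormal sd of baseline gene abundances.
#' @param nMitoGenes number of mitochondrial genes (named `mt:...`).
#' @param mitoFractionRange range of the per-cell mitochondrial UMI
#'   fraction (drawn uniformly).
#' @param nAmbientBarcodes number of ambient (cell-free) barcodes drawn
#'   from the pooled expression profile.
#' @param ambientDepthFactor ambient depth as a fraction of `meanDepth`,
#'   in (0, 1).
#' @param stressGeneCount number of dissociation-stress genes (sampled
#'   from the upper half of baseline abundance, as stress-response genes
#'   are well expressed).
#' @param stressLogfc natural-log fold change applied to stress genes in
#'   the single-cell counts only.
#' @param regulons list of regulons, each a `list(tf=, nTargets=, active=)`
#'   with `active` a vector of subtype labels (`"s1"`, ...); target genes
#'   are assigned by the simulator from the free gene pool and given a low
#'   baseline (`regulonBaseRel` times the average gene) so the program is
#'   close to on/off.
#' @param regulonLogfc natural-log fold change of regulon targets in their
#'   active subtypes.
#' @param regulonBaseRel baseline abundance of regulon targets relative to
#'   the average gene.
#' @param ccGeneSets cell-cycle phase gene sets, as [phaseGeneSets()].
#' @param cyclingSubtypes subtype labels with an elevated cell-cycle
#'   program.
#' @param ccLogfc natural-log fold change of cell-cycle genes in cycling
#'   subtypes.
#' @param libraryTimepoint optional character vector, timepoint per
#'   library (default all `"96h"`).
#' @param libraryCondition optional character vector, condition per
#'   library (default all `"normal"`).
#' @param seed integer RNG seed; a fixed seed makes [simulateCohort()]
#'   fully deterministic.
#'
#' @return a validated list of class `SynthConfig`.
#' @seealso [simulateCohort()], [makeBulkProfile()]
#' @export
#' @examples
#' cfg <- synthConfig(nCells = 300, nGenes = 200, nAmbientBarcodes = 50)
#' cohort <- simulateCohort(cfg)
synthConfig <- function(nCells = 2000L,
                        nGenes = 1000L,
                        nSubtypes = 6L,
                        subtypeProportions = c(0.2, 0.2, 0.175, 0.175,
                                               0.15, 0.1),
                        supergroupMap = c(1L, 1L, 2L, 2L, 3L, 4L),
                        nLibraries = 4L,
                        batchLogfcSd = 0.15,
                        markerGenesPerSubtype = c(30L, 30L, 30L, 250L),
                        markerLogfc = log(10),
                        dupMarkerCount = 5L,
                        dupLogfc = 0.7,
                        nbDispersion = 0.5,
                        meanDepth = 2000,
                        depthLogsd = 0.25,
                        baseLogSd = 1.5,
                        nMitoGenes = 10L,
                        mitoFractionRange = c(0.01, 0.08),
                        nAmbientBarcodes = 500L,
                        ambientDepthFactor = 0.02,
                        stressGeneCount = 20L,
                        stressLogfc = log(20),
                        regulons = list(),
                        regulonLogfc = log(50),
                        regulonBaseRel = 0.01,
                        ccGeneSets = phaseGeneSets(),
                        cyclingSubtypes = "s1",
                        ccLogfc = log(4),
                        libraryTimepoint = NULL,
                        libraryCondition = NULL,
                        seed = 1L) {
  cfg <- list(
    nCells = as.integer(nCells), nGenes = as.integer(nGenes),
    nSubtypes = as.integer(nSubtypes),
    subtypeProportions = as.numeric(subtypeProportions),
    supergroupMap = as.integer(supergroupMap),
    nLibraries = as.integer(nLibraries), batchLogfcSd = batchLogfcSd,
    markerGenesPerSubtype = as.integer(markerGenesPerSubtype),
    markerLogfc = markerLogfc, dupMarkerCount = as.integer(dupMarkerCount),
    dupLogfc = dupLogfc, nbDispersion = nbDispersion,
    meanDepth = meanDepth, depthLogsd = depthLogsd, baseLogSd = baseLogSd,
    nMitoGenes = as.integer(nMitoGenes),
    mitoFractionRange = as.numeric(mitoFractionRange),
    nAmbientBarcodes = as.integer(nAmbientBarcodes),
    ambientDepthFactor = ambientDepthFactor,
    stressGeneCount = as.integer(stressGeneCount),
    stressLogfc = stressLogfc, regulons = regulons,
    regulonLogfc = regulonLogfc, regulonBaseRel = regulonBaseRel,
    ccGeneSets = ccGeneSets,
    cyclingSubtypes = as.character(cyclingSubtypes), ccLogfc = ccLogfc,
    libraryTimepoint = libraryTimepoint,
    libraryCondition = libraryCondition, seed = as.integer(seed)
  )
  class(cfg) <- "SynthConfig"
  validateSynthConfig(cfg)
  cfg
}

#' @rdname synthConfig
#' @param config a `SynthConfig`
#' @export
validateSynthConfig <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  with(config, {
    if (nCells < 1L || nGenes < 1L || nSubtypes < 1L || nLibraries < 1L ||
        nAmbientBarcodes < 0L || stressGeneCount < 0L || nMitoGenes < 0L ||
        dupMarkerCount < 0L) {
      stop("all counts in a SynthConfig must be non-negative", call. = FALSE)
    }
    if (length(subtypeProportions) != nSubtypes ||
        abs(sum(subtypeProportions) - 1) > 1e-9 ||
        any(subtypeProportions < 0)) {
      stop("subtypeProportions must be a length-nSubtypes probability ",
           "vector summing to 1", call. = FALSE)
    }
    if (length(supergroupMap) != nSubtypes) {
      stop("supergroupMap must assign every subtype to a coarse group",
           call. = FALSE)
    }
    nCoarse <- length(unique(supergroupMap))
    if (!length(markerGenesPerSubtype) %in% c(1L, nCoarse)) {
      stop("markerGenesPerSubtype must be scalar or one value per coarse ",
           "group", call. = FALSE)
    }
    if (nbDispersion <= 0) stop("nbDispersion must be > 0", call. = FALSE)
    if (ambientDepthFactor <= 0 || ambientDepthFactor >= 1) {
      stop("ambientDepthFactor must lie in (0, 1)", call. = FALSE)
    }
    if (length(mitoFractionRange) != 2L || any(mitoFractionRange < 0) ||
        any(mitoFractionRange > 1) ||
        mitoFractionRange[1L] > mitoFractionRange[2L]) {
      stop("mitoFractionRange must be an interval within [0, 1]",
           call. = FALSE)
    }
    mpg <- rep_len(markerGenesPerSubtype, nCoarse)
    dupSubtypes <- sum(table(supergroupMap)[table(supergroupMap) > 1L])
    nCc <- length(unlist(ccGeneSets))
    nReg <- sum(vapply(regulons, function(r) as.integer(r$nTargets),
                       integer(1)))
    demand <- nMitoGenes + nCc + sum(mpg) +
      dupSubtypes * dupMarkerCount + stressGeneCount + nReg
    if (demand > nGenes) {
      stop(sprintf(paste0("configuration error: gene demands (%d) exceed ",
                          "nGenes (%d)"), demand, nGenes), call. = FALSE)
    }
    for (r in regulons) {
      if (is.null(r$tf) || is.null(r$nTargets) || is.null(r$active)) {
        stop("each regulon needs fields tf, nTargets and active",
             call. = FALSE)
      }
      bad <- setdiff(r$active, paste0("s", seq_len(nSubtypes)))
      if (length(bad) > 0L) {
        stop("regulon active subtypes must be valid subtype labels",
             call. = FALSE)
      }
    }
  })
  invisible(config)
}

#' Simulate a droplet scRNA-seq cohort with known ground truth
#'
#' Draws a genes-by-barcodes UMI count matrix from a negative-binomial
#' model: per-gene lognormal baseline abundance, multiplicative subtype
#' marker programs, per-library batch effects, per-cell lognormal depth, a
#' per-cell mitochondrial fraction, a dissociation-stress program applied
#' to the single-cell counts only, regulon target programs elevated in
#' their active subtypes, and ambient barcodes drawn from the pooled
#' profile at a small depth.  The same `SynthConfig` always yields an
#' identical cohort.
#'
#' @param config a [synthConfig()].
#' @return a list with components `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment] with a sparse `counts`
#'   assay and per-barcode `library`, `timepoint`, `condition` and
#'   `ambient` columns) and `truth` (a [SyntheticTruth-class]).
#' @export
simulateCohort <- function(config) {
  validateSynthConfig(config)
  .withSeed(config$seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  G <- config$nGenes
  K <- config$nSubtypes
  L <- config$nLibraries
  subtypeLabels <- paste0("s", seq_len(K))
  coarseIds <- config$supergroupMap
  coarseLabels <- paste0("g", coarseIds)
  coarseLevels <- unique(coarseLabels)

  # gene universe: mitochondrial block, cell-cycle symbols, generic genes
  ccGenes <- unlist(config$ccGeneSets, use.names = FALSE)
  geneNames <- sprintf("gene%05d", seq_len(G))
  if (config$nMitoGenes > 0L) {
    geneNames[seq_len(config$nMitoGenes)] <-
      sprintf("mt:gene%d", seq_len(config$nMitoGenes))
  }
  if (length(ccGenes) > 0L) {
    geneNames[config$nMitoGenes + seq_along(ccGenes)] <- ccGenes
  }
  mitoIdx <- seq_len(config$nMitoGenes)
  ccIdx <- config$nMitoGenes + seq_along(ccGenes)

  # baseline relative abundances
  w <- stats::rlnorm(G, meanlog = 0, sdlog = config$baseLogSd)

  pool <- setdiff(seq_len(G), c(mitoIdx, ccIdx))

  # stress genes come from the well-expressed half of the pool
  stressIdx <- integer(0)
  if (config$stressGeneCount > 0L) {
    eligible <- pool[w[pool] >= stats::median(w[pool])]
    stressIdx <- sort(sample(eligible, config$stressGeneCount))
    pool <- setdiff(pool, stressIdx)
  }

  # coarse-group marker programs
  nCoarse <- length(coarseLevels)
  mpg <- rep_len(config$markerGenesPerSubtype, nCoarse)
  coarseMarkers <- vector("list", nCoarse)
  names(coarseMarkers) <- coarseLevels
  for (i in seq_len(nCoarse)) {
    coarseMarkers[[i]] <- sort(sample(pool, mpg[i]))
    pool <- setdiff(pool, coarseMarkers[[i]])
  }

  # private markers for members of near-duplicate coarse groups
  privateMarkers <- vector("list", K)
  names(privateMarkers) <- subtypeLabels
  multi <- names(table(coarseIds))[table(coarseIds) > 1L]
  for (s in seq_len(K)) {
    if (as.character(coarseIds[s]) %in% multi && config$dupMarkerCount > 0L) {
      privateMarkers[[s]] <- sort(sample(pool, config$dupMarkerCount))
      pool <- setdiff(pool, privateMarkers[[s]])
    } else {
      privateMarkers[[s]] <- integer(0)
    }
  }

  # regulon targets: low-baseline, near-binary programs
  regulonTargets <- list()
  for (r in config$regulons) {
    idx <- sort(sample(pool, as.integer(r$nTargets)))
    pool <- setdiff(pool, idx)
    w[idx] <- config$regulonBaseRel * mean(w)
    regulonTargets[[r$tf]] <- idx
  }

  # subtype mean programs (relative abundance, unnormalized)
  M <- matrix(w, nrow = G, ncol = K)
  for (s in seq_len(K)) {
    cm <- coarseMarkers[[coarseLabels[s]]]
    M[cm, s] <- M[cm, s] * exp(config$markerLogfc)
    pm <- privateMarkers[[s]]
    M[pm, s] <- M[pm, s] * exp(config$dupLogfc)
    if (subtypeLabels[s] %in% config$cyclingSubtypes && length(ccIdx) > 0L) {
      M[ccIdx, s] <- M[ccIdx, s] * exp(config$ccLogfc)
    }
  }
  for (r in config$regulons) {
    act <- match(r$active, subtypeLabels)
    idx <- regulonTargets[[r$tf]]
    M[idx, act] <- M[idx, act] * exp(config$regulonLogfc)
  }

  # per-library batch effects
  B <- matrix(exp(stats::rnorm(G * L, 0, config$batchLogfcSd)), G, L)

  # cell-level assignments
  n <- config$nCells
  subtypeOf <- sample(seq_len(K), n, replace = TRUE,
                      prob = config$subtypeProportions)
  libOf <- sample(seq_len(L), n, replace = TRUE)
  depth <- stats::rlnorm(n, log(config$meanDepth) - config$depthLogsd^2 / 2,
                         config$depthLogsd)
  fMito <- stats::runif(n, config$mitoFractionRange[1L],
                        config$mitoFractionRange[2L])

  P <- M[, subtypeOf, drop = FALSE] * B[, libOf, drop = FALSE]
  if (length(mitoIdx) > 0L) {
    sm <- colSums(P[mitoIdx, , drop = FALSE])
    snm <- colSums(P[-mitoIdx, , drop = FALSE])
    P[mitoIdx, ] <- sweep(P[mitoIdx, , drop = FALSE], 2, fMito / sm, "*")
    P[-mitoIdx, ] <- sweep(P[-mitoIdx, , drop = FALSE], 2,
                           (1 - fMito) / snm, "*")
  } else {
    P <- sweep(P, 2, colSums(P), "/")
  }
  mu <- sweep(P, 2, depth, "*")
  # stress program inflates the single-cell counts on top of the cell's
  # baseline budget; the matched bulk profile carries no such term
  if (length(stressIdx) > 0L) {
    mu[stressIdx, ] <- mu[stressIdx, ] * exp(config$stressLogfc)
  }
  size <- 1 / config$nbDispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size), G, n)

  # ambient barcodes: pooled cell profile at a small depth
  nAmb <- config$nAmbientBarcodes
  if (nAmb > 0L) {
    pooled <- rowSums(mu) / sum(mu)
    ambDepth <- stats::rlnorm(
      nAmb,
      log(config$ambientDepthFactor * config$meanDepth) -
        config$depthLogsd^2 / 2,
      config$depthLogsd)
    muAmb <- outer(pooled, ambDepth)
    ambCounts <- matrix(stats::rnbinom(length(muAmb), mu = muAmb,
                                       size = size), G, nAmb)
    ambLib <- sample(seq_len(L), nAmb, replace = TRUE)
  } else {
    ambCounts <- matrix(integer(0), G, 0L)
    ambLib <- integer(0)
  }

  barcodes <- c(sprintf("cell%05d", seq_len(n)),
                if (nAmb > 0L) sprintf("amb%05d", seq_len(nAmb)))
  all <- cbind(counts, ambCounts)
  dimnames(all) <- list(geneNames, barcodes)
  spmat <- methods::as(methods::as(Matrix::Matrix(all, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")

  tpOf <- config$libraryTimepoint
  if (is.null(tpOf)) tpOf <- rep("96h", L)
  condOf <- config$libraryCondition
  if (is.null(condOf)) condOf <- rep("normal", L)
  libAll <- c(libOf, ambLib)
  cd <- S4Vectors::DataFrame(
    library = paste0("lib", libAll),
    timepoint = tpOf[libAll],
    condition = condOf[libAll],
    ambient = c(rep(FALSE, n), rep(TRUE, nAmb)),
    row.names = barcodes)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = spmat), colData = cd)

  mkMap <- lapply(seq_len(K), function(s) {
    geneNames[c(coarseMarkers[[coarseLabels[s]]], privateMarkers[[s]])]
  })
  names(mkMap) <- subtypeLabels
  regTruth <- lapply(config$regulons, function(r) as.character(r$active))
  names(regTruth) <- vapply(config$regulons, function(r) r$tf, character(1))
  regTargetMap <- lapply(regulonTargets, function(idx) geneNames[idx])

  truth <- methods::new(
    "SyntheticTruth",
    subtype = stats::setNames(
      c(subtypeLabels[subtypeOf], rep(NA_character_, nAmb)), barcodes),
    library = stats::setNames(paste0("lib", libAll), barcodes),
    coarseGroup = stats::setNames(
      c(coarseLabels[subtypeOf], rep(NA_character_, nAmb)), barcodes),
    ambient = stats::setNames(c(rep(FALSE, n), rep(TRUE, nAmb)), barcodes),
    stressGenes = geneNames[stressIdx],
    stressLogfc = config$stressLogfc,
    markerMap = mkMap,
    regulonTruth = regTruth,
    regulonTargets = regTargetMap,
    cyclingSubtypes = config$cyclingSubtypes,
    ccGenes = geneNames[ccIdx])

  list(sce = sce, truth = truth)
}

#' Matched bulk profile of a simulated cohort
#'
#' Builds the bulk RNA-seq gene-count table a dissociation-free assay of
#' the same tissue would yield: per-gene sums over non-ambient cells with
#' the single-cell-only stress multiplier divided out.  This is the
#' reference table consumed by [foldChangeTable()].
#'
#' @param sce the `SingleCellExperiment` returned by [simulateCohort()].
#' @param truth the matching [SyntheticTruth-class].
#' @return a `data.frame` with columns `gene` and `count`.
#' @export
makeBulkProfile <- function(sce, truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  bcs <- colnames(sce)
  if (!all(bcs %in% names(truth@ambient)) ||
      !all(truth@stressGenes %in% rownames(sce))) {
    stop("truth/matrix mismatch: barcodes or gene sets do not agree",
         call. = FALSE)
  }
  keep <- bcs[!truth@ambient[bcs]]
  bulk <- Matrix::rowSums(.counts(sce)[, keep, drop = FALSE])
  sg <- truth@stressGenes
  bulk[sg] <- bulk[sg] / exp(truth@stressLogfc)
  data.frame(gene = rownames(sce), count = as.numeric(bulk),
             row.names = NULL, stringsAsFactors = FALSE)
}
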