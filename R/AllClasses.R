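#' @import methods
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

# ---------------------------------------------------------------------------
# SyntheticTruth
# ---------------------------------------------------------------------------

#' Ground truth of a simulated cohort
#'
#' Records what [simulateCohort()] planted: the subtype and coarse-group
#' label of every cell barcode, which barcodes are ambient, the
#' dissociation-stress gene set, the per-subtype marker map and the
#' regulon-to-subtype activity map.  Ambient barcodes carry `NA` subtype
#' and coarse-group labels.
#'
#' @slot subtype named character vector, subtype per barcode (`NA` for
#'   ambient barcodes).
#' @slot library named character vector, library of origin per barcode.
#' @slot coarseGroup named character vector, coarse group per barcode;
#'   a deterministic function of `subtype` through the supergroup map.
#' @slot ambient named logical vector, ambient flag per barcode.
#' @slot stressGenes character, planted stress-program genes.
#' @slot stressLogfc numeric(1), natural-log fold change of the stress
#'   program in the single-cell counts.
#' @slot markerMap named list, subtype -> planted marker genes.
#' @slot regulonTruth named list, transcription factor -> subtypes in which
#'   its regulon is active.
#' @slot regulonTargets named list, transcription factor -> planted target
#'   genes (the regulon definitions a caller consumes).
#' @slot cyclingSubtypes character, subtypes with an elevated cell-cycle
#'   program.
#' @slot ccGenes character, the planted cell-cycle genes.
#'
#' @seealso [simulateCohort()], [makeBulkProfile()]
#' @export
setClass("SyntheticTruth",
  representation(
    subtype = "character",
    library = "character",
    coarseGroup = "character",
    ambient = "logical",
    stressGenes = "character",
    stressLogfc = "numeric",
    markerMap = "list",
    regulonTruth = "list",
    regulonTargets = "list",
    cyclingSubtypes = "character",
    ccGenes = "character"
  )
)

setValidity("SyntheticTruth", function(object) {
  n <- length(object@subtype)
  if (length(object@library) != n || length(object@coarseGroup) != n ||
      length(object@ambient) != n) {
    return("per-barcode slots must have equal length")
  }
  if (any(is.na(object@subtype) != object@ambient)) {
    return("exactly the ambient barcodes must carry NA subtype labels")
  }
  if (any(is.na(object@coarseGroup) != object@ambient)) {
    return("exactly the ambient barcodes must carry NA coarse-group labels")
  }
  TRUE
})

#' @describeIn SyntheticTruth subtype label per barcode
#' @param object,x a `SyntheticTruth`
#' @export
setGeneric("cellSubtype", function(object) standardGeneric("cellSubtype"))
#' @export
setMethod("cellSubtype", "SyntheticTruth", function(object) object@subtype)

#' @describeIn SyntheticTruth coarse-group label per barcode
#' @export
setGeneric("coarseGroup", function(object) standardGeneric("coarseGroup"))
#' @export
setMethod("coarseGroup", "SyntheticTruth", function(object) object@coarseGroup)

#' @describeIn SyntheticTruth ambient flag per barcode
#' @export
setGeneric("ambientFlag", function(object) standardGeneric("ambientFlag"))
#' @export
setMethod("ambientFlag", "SyntheticTruth", function(object) object@ambient)

#' @describeIn SyntheticTruth planted stress genes
#' @export
setGeneric("stressGenes", function(object) standardGeneric("stressGenes"))
#' @export
setMethod("stressGenes", "SyntheticTruth", function(object) object@stressGenes)

#' @describeIn SyntheticTruth subtype -> marker gene map
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))
#' @export
setMethod("markerMap", "SyntheticTruth", function(object) object@markerMap)

#' @describeIn SyntheticTruth TF -> active subtype map
#' @export
setGeneric("regulonTruth", function(object) standardGeneric("regulonTruth"))
#' @export
setMethod("regulonTruth", "SyntheticTruth", function(object) object@regulonTruth)

#' @describeIn SyntheticTruth TF -> planted target gene map
#' @export
setGeneric("regulonTargets", function(object) standardGeneric("regulonTargets"))
#' @export
setMethod("regulonTargets", "SyntheticTruth", function(object) object@regulonTargets)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@subtype), "barcodes (",
      sum(object@ambient), "ambient ),",
      length(unique(stats::na.omit(object@subtype))), "subtypes,",
      length(unique(stats::na.omit(object@coarseGroup))), "coarse groups\n")
  cat("  stress genes:", length(object@stressGenes),
      "| regulons:", length(object@regulonTruth),
      "| cycling subtypes:",
      paste(object@cyclingSubtypes, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# QcReport
# ---------------------------------------------------------------------------

#' Per-rule accounting of sequential cell filtering
#'
#' Produced by [qcFilterCells()].  Rules are applied in order (knee /
#' minimum reads, detected-gene bounds, UMI outlier, mitochondrial
#' fraction); each barcode is counted once, at the first rule it fails,
#' so the input count always equals retained plus the per-rule removals.
#'
#' @slot nIn integer(1), barcodes entering the filter.
#' @slot removed named integer, removals per rule
#'   (`knee`, `genes`, `umi`, `mito`).
#' @slot nRetained integer(1), barcodes surviving all rules.
#'
#' @seealso [qcFilterCells()]
#' @export
setClass("QcReport",
  representation(nIn = "integer", removed = "integer", nRetained = "integer")
)

setValidity("QcReport", function(object) {
  if (!identical(sort(names(object@removed)),
                 sort(c("knee", "genes", "umi", "mito")))) {
    return("removed must be named knee/genes/umi/mito")
  }
  if (object@nIn != object@nRetained + sum(object@removed)) {
    return("conservation violated: nIn != nRetained + sum(removed)")
  }
  TRUE
})

#' @describeIn QcReport barcodes retained after all rules
#' @param object a `QcReport`
#' @export
setGeneric("nRetained", function(object) standardGeneric("nRetained"))
#' @export
setMethod("nRetained", "QcReport", function(object) object@nRetained)

#' @describeIn QcReport named per-rule removal counts
#' @export
setGeneric("removedCounts", function(object) standardGeneric("removedCounts"))
#' @export
setMethod("removedCounts", "QcReport", function(object) object@removed)

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", object@nIn, "barcodes in,", object@nRetained,
      "retained\n  removed:",
      paste(sprintf("%s=%d", names(object@removed), object@removed),
            collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# PseudobulkProfile
# ---------------------------------------------------------------------------

#' Per-group aggregated expression profiles
#'
#' Genes-by-groups summed raw counts together with their log1p
#' counts-per-million transform and the group sizes.  Produced by
#' [pseudobulk()]; consumed by [correlationMatrix()] and the super-group
#' exclusion/merge loops.
#'
#' @slot rawSums numeric matrix, genes x groups summed counts.
#' @slot logCPM numeric matrix, `log1p(CPM)` of `rawSums`.
#' @slot sizes named integer, cells per group.
#' @export
setClass("PseudobulkProfile",
  representation(rawSums = "matrix", logCPM = "matrix", sizes = "integer")
)

setValidity("PseudobulkProfile", function(object) {
  if (!identical(dim(object@rawSums), dim(object@logCPM))) {
    return("rawSums and logCPM must have identical dimensions")
  }
  if (!identical(colnames(object@rawSums), names(object@sizes))) {
    return("group names of rawSums and sizes must match")
  }
  if (any(object@sizes < 1L)) {
    return("empty group in pseudobulk profile")
  }
  TRUE
})

#' @describeIn PseudobulkProfile genes x groups summed counts
#' @param object a `PseudobulkProfile`
#' @export
setGeneric("rawSums", function(object) standardGeneric("rawSums"))
#' @export
setMethod("rawSums", "PseudobulkProfile", function(object) object@rawSums)

#' @describeIn PseudobulkProfile genes x groups log1p-CPM matrix
#' @export
setGeneric("logCPM", function(object) standardGeneric("logCPM"))
#' @export
setMethod("logCPM", "PseudobulkProfile", function(object) object@logCPM)

#' @describeIn PseudobulkProfile named group sizes
#' @export
setGeneric("groupSizes", function(object) standardGeneric("groupSizes"))
#' @export
setMethod("groupSizes", "PseudobulkProfile", function(object) object@sizes)

setMethod("show", "PseudobulkProfile", function(object) {
  cat("PseudobulkProfile:", nrow(object@rawSums), "genes x",
      ncol(object@rawSums), "groups\n  sizes:",
      paste(sprintf("%s=%d", names(object@sizes), object@sizes),
            collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SupergroupSolution
# ---------------------------------------------------------------------------

#' Result of the resolution-optimized super-group search
#'
#' Returned by [optimizeResolution()]: the resolution whose pruned and
#' merged partition maximizes the number of differentially expressed
#' genes, the fine cluster labels at that resolution, the clusters pruned
#' by the correlation floor, the fine-cluster to super-group map, the DEG
#' count of the winning partition and the full per-resolution trace.
#'
#' @slot resolution numeric(1), the selected resolution.
#' @slot fineLabels named character, fine cluster per cell at the selected
#'   resolution.
#' @slot excludedClusters character, fine clusters pruned because their
#'   pseudo-bulk correlation to the remainder stayed below the floor.
#' @slot supergroupMap named character, retained fine cluster ->
#'   super-group.
#' @slot degCount integer(1), unique DEGs among super-groups at the
#'   selected resolution.
#' @slot trace data.frame with one row per swept resolution
#'   (`resolution`, `nClusters`, `nSupergroups`, `degCount`).
#'
#' @seealso [optimizeResolution()], [mergeSupergroups()],
#'   [excludeUncorrelated()]
#' @export
setClass("SupergroupSolution",
  representation(
    resolution = "numeric",
    fineLabels = "character",
    excludedClusters = "character",
    supergroupMap = "character",
    degCount = "integer",
    trace = "data.frame"
  )
)

setValidity("SupergroupSolution", function(object) {
  if (length(intersect(object@excludedClusters,
                       names(object@supergroupMap))) > 0L) {
    return("excluded clusters cannot appear in the supergroup map")
  }
  retained <- setdiff(unique(object@fineLabels), object@excludedClusters)
  if (!all(retained %in% names(object@supergroupMap))) {
    return("every retained fine cluster must map to a super-group")
  }
  if (object@degCount < 0L) {
    return("degCount must be non-negative")
  }
  TRUE
})

#' @describeIn SupergroupSolution the selected resolution
#' @param object a `SupergroupSolution`
#' @export
setGeneric("chosenResolution",
           function(object) standardGeneric("chosenResolution"))
#' @export
setMethod("chosenResolution", "SupergroupSolution",
          function(object) object@resolution)

#' @describeIn SupergroupSolution named fine cluster labels per cell
#' @export
setGeneric("fineLabels", function(object) standardGeneric("fineLabels"))
#' @export
setMethod("fineLabels", "SupergroupSolution", function(object) object@fineLabels)

#' @describeIn SupergroupSolution pruned fine clusters
#' @export
setGeneric("excludedClusters",
           function(object) standardGeneric("excludedClusters"))
#' @export
setMethod("excludedClusters", "SupergroupSolution",
          function(object) object@excludedClusters)

#' @describeIn SupergroupSolution retained fine cluster -> super-group map
#' @export
setGeneric("supergroupMap", function(object) standardGeneric("supergroupMap"))
#' @export
setMethod("supergroupMap", "SupergroupSolution",
          function(object) object@supergroupMap)

#' @describeIn SupergroupSolution DEG count of the winning partition
#' @export
setGeneric("degCountOf", function(object) standardGeneric("degCountOf"))
#' @export
setMethod("degCountOf", "SupergroupSolution", function(object) object@degCount)

#' @describeIn SupergroupSolution per-resolution sweep trace
#' @export
setGeneric("sweepTrace", function(object) standardGeneric("sweepTrace"))
#' @export
setMethod("sweepTrace", "SupergroupSolution", function(object) object@trace)

#' @describeIn SupergroupSolution per-cell super-group labels (`NA` for
#'   cells in excluded clusters)
#' @export
setGeneric("cellSupergroups",
           function(object) standardGeneric("cellSupergroups"))
#' @export
setMethod("cellSupergroups", "SupergroupSolution", function(object) {
  out <- rep(NA_character_, length(object@fineLabels))
  names(out) <- names(object@fineLabels)
  keep <- object@fineLabels %in% names(object@supergroupMap)
  out[keep] <- object@supergroupMap[object@fineLabels[keep]]
  out
})

setMethod("show", "SupergroupSolution", function(object) {
  cat("SupergroupSolution: resolution", object@resolution, "\n")
  cat("  fine clusters:", length(unique(object@fineLabels)),
      "| excluded:", length(object@excludedClusters),
      "| super-groups:", length(unique(object@supergroupMap)),
      "| DEGs:", object@degCount, "\n")
  cat("  swept", nrow(object@trace), "resolutions\n")
})

# ---------------------------------------------------------------------------
# ConsensusResult
# ---------------------------------------------------------------------------

#' Balanced-resampling consensus of regulon activity
#'
#' Returned by [runConsensus()]: per-TF counts of trials in which the
#' activity caller declared the TF active on a balanced per-subcluster
#' sample, together with the consensus set of TFs reaching the hit
#' threshold and the reproducible per-trial cell samples.
#'
#' @slot hits named integer, per-TF hit counts in `[0, trials]`.
#' @slot trials integer(1), number of resampling trials attempted.
#' @slot minHits integer(1), hit threshold for consensus membership.
#' @slot consensus character, TFs with `hits >= minHits`.
#' @slot trialSamples list of character vectors, cells drawn per trial.
#' @slot failedTrials integer(1), trials in which the caller errored.
#'
#' @seealso [runConsensus()], [balancedSample()], [referenceCaller()]
#' @export
setClass("ConsensusResult",
  representation(
    hits = "integer",
    trials = "integer",
    minHits = "integer",
    consensus = "character",
    trialSamples = "list",
    failedTrials = "integer"
  )
)

setValidity("ConsensusResult", function(object) {
  if (any(object@hits < 0L) || any(object@hits > object@trials)) {
    return("hit counts must lie in [0, trials]")
  }
  expected <- names(object@hits)[object@hits >= object@minHits]
  if (!setequal(object@consensus, expected)) {
    return("consensus set must equal {TF : hits >= minHits}")
  }
  TRUE
})

#' @describeIn ConsensusResult named per-TF hit counts
#' @param object a `ConsensusResult`
#' @export
setGeneric("tfHits", function(object) standardGeneric("tfHits"))
#' @export
setMethod("tfHits", "ConsensusResult", function(object) object@hits)

#' @describeIn ConsensusResult TFs reaching the hit threshold
#' @export
setGeneric("consensusSet", function(object) standardGeneric("consensusSet"))
#' @export
setMethod("consensusSet", "ConsensusResult", function(object) object@consensus)

#' @describeIn ConsensusResult per-trial sampled cell lists
#' @export
setGeneric("trialSamples", function(object) standardGeneric("trialSamples"))
#' @export
setMethod("trialSamples", "ConsensusResult", function(object) object@trialSamples)

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult:", length(object@hits), "TFs over", object@trials,
      "trials (", object@failedTrials, "failed )\n")
  cat("  consensus (hits >=", object@minHits, "):",
      if (length(object@consensus)) paste(object@consensus, collapse = ", ")
      else "<none>", "\n")
})
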