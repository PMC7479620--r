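test_that("the activity gene filter reproduces its threshold arithmetic", {
  set.seed(2)
  m <- matrix(rpois(50 * 348, 2), 50, 348)
  m[1, ] <- 0                     # zero-total gene: removed
  m[2, ] <- rpois(348, 30)        # deep, everywhere: kept
  filt <- activityGeneFilter(makeSce(m))
  expect_equal(filt$umiThreshold, 31.32)
  expect_equal(filt$minCells, 10.44)
  expect_false("g001" %in% filt$genes)
  expect_true("g002" %in% filt$genes)
  expect_error(activityGeneFilter(makeSce(m), fraction = 1.2), "fraction")
})

test_that("balanced samples draw floor(f * min) cells from every group", {
  sizes <- c(63, rep(200, 27))
  labs <- stats::setNames(rep(paste0("sc", 1:28), times = sizes),
                          sprintf("c%05d", seq_len(sum(sizes))))
  cells <- balancedSample(labs, 2 / 3, seed = 9)
  expect_equal(attr(cells, "k"), 42L)
  expect_equal(length(cells), 28L * 42L)  # 1176
  expect_false(any(duplicated(cells)))
  drawn <- table(labs[cells])
  expect_true(all(drawn == 42L))

  # reproducible per seed, different across seeds
  expect_identical(balancedSample(labs, 2 / 3, 9), cells)
  expect_false(identical(as.character(balancedSample(labs, 2 / 3, 10)),
                         as.character(cells)))

  # exhaustive draw at fraction 1 on equal groups
  labsEq <- stats::setNames(rep(c("a", "b"), each = 5), paste0("c", 1:10))
  expect_setequal(balancedSample(labsEq, 1, 1), names(labsEq))

  expect_error(balancedSample(labsEq, 0.1, 1), "too small")
})

test_that("the reference caller flags planted contrasts only", {
  set.seed(14)
  n <- 120L
  m <- matrix(rpois(300 * n, 3), 300, n)
  labs <- stats::setNames(rep(c("A", "B", "C", "D"), each = 30),
                          sprintf("c%03d", 1:n))

  # uniform expression everywhere: no regulon is active
  sce0 <- normalizeCounts(makeSce(m))
  act0 <- referenceCaller(sce0, colnames(sce0), labs,
                          list(tfFlat = rownames(sce0)[21:30]))
  expect_false("tfFlat" %in% act0)

  # targets at 4x in one group: active
  m[1:10, 1:30] <- rpois(10 * 30, 12)
  sce <- normalizeCounts(makeSce(m))
  act <- referenceCaller(sce, colnames(sce), labs,
                         list(tfUp = rownames(sce)[1:10]))
  expect_true("tfUp" %in% act)

  # zero-count subset: every regulon is filtered out, nothing active
  z <- makeSce(matrix(0L, 20, 10))
  assay(z, "logcounts") <- counts(z) * 1
  expect_equal(suppressWarnings(
    referenceCaller(z, colnames(z), stats::setNames(rep(c("A", "B"), 5),
                                                    colnames(z)),
                    list(tf = rownames(z)[1:6]))), character(0))
})

test_that("consensus tallies are exact for constant callers", {
  ch <- smallCohort()
  cells <- realCells(ch)
  sce <- ch$sce[, cells]
  labs <- cellSubtype(ch$truth)[cells]
  regs <- list(tfA = rownames(sce)[1:6], tfB = rownames(sce)[7:12])
  cfg <- consensusConfig(trials = 10L, minHits = 3L, seed = 5L)

  always <- function(sce, cells, labels, regulons, ...) "tfA"
  res <- runConsensus(sce, labs, regs, cfg, caller = always)
  expect_equal(unname(tfHits(res)["tfA"]), 10L)
  expect_equal(unname(tfHits(res)["tfB"]), 0L)
  expect_equal(consensusSet(res), "tfA")

  never <- function(sce, cells, labels, regulons, ...) character(0)
  expect_equal(consensusSet(runConsensus(sce, labs, regs, cfg,
                                         caller = never)), character(0))

  # reproducibility of samples and tallies
  res2 <- runConsensus(sce, labs, regs, cfg, caller = always)
  expect_identical(tfHits(res2), tfHits(res))
  expect_identical(trialSamples(res2), trialSamples(res))

  # consensus is monotone non-increasing in the hit threshold
  resRand <- runConsensus(sce, labs, regs,
                          consensusConfig(trials = 10L, minHits = 1L,
                                          seed = 5L),
                          caller = function(sce, cells, labels, regulons,
                                            ...) {
                            sample(c("tfA", "tfB"),
                                   sample(0:2, 1))
                          })
  h <- tfHits(resRand)
  expect_true(all(names(h)[h >= 5L] %in% names(h)[h >= 1L]))

  # persistent caller failure aborts
  broken <- function(sce, cells, labels, regulons, ...) stop("boom")
  expect_error(runConsensus(sce, labs, regs, cfg, caller = broken),
               "10%")
})

test_that("balanced resampling rescues a small-population regulon", {
  cfg <- synthConfig(
    nCells = 3000L, nGenes = 300L, nSubtypes = 5L,
    subtypeProportions = c(0.32, 0.28, 0.2, 0.179, 0.021),
    supergroupMap = 1:5, markerGenesPerSubtype = 10L,
    nAmbientBarcodes = 0L, stressGeneCount = 0L,
    regulons = list(list(tf = "tfSmall", nTargets = 10L, active = "s5"),
                    list(tf = "tfBig", nTargets = 10L, active = "s1")),
    regulonBaseRel = 0.01 * 300 / 1000,  # same baseline counts as default
    seed = 88L)
  ch <- simulateCohort(cfg)
  sce <- normalizeCounts(ch$sce)
  labs <- cellSubtype(ch$truth)[colnames(sce)]
  regTargets <- regulonTargets(ch$truth)
  expect_setequal(names(regTargets), c("tfSmall", "tfBig"))

  res <- runConsensus(sce, labs, regTargets,
                      consensusConfig(trials = 20L, minHits = 5L,
                                      seed = 31L))
  expect_true("tfSmall" %in% consensusSet(res))

  # a single whole-data call misses the small-population regulon
  whole <- suppressWarnings(
    referenceCaller(sce, colnames(sce), labs, regTargets))
  expect_false("tfSmall" %in% whole)
})

test_that("group-by-stage profiles drop minor combinations and center", {
  set.seed(6)
  m <- matrix(rpois(30 * 200, 4), 30, 200)
  sce <- normalizeCounts(makeSce(m))
  labs <- stats::setNames(c(rep("A", 120), rep("B", 75), rep("C", 5)),
                          colnames(sce))
  tps <- stats::setNames(rep("t1", 200), colnames(sce))
  prof <- groupProfiles(sce, labs, tps, minorGroupFraction = 0.05)
  expect_equal(attr(prof, "cellThreshold"), 10)
  expect_equal(attr(prof, "dropped"), "C.t1")
  expect_setequal(colnames(prof), c("A.t1", "B.t1"))

  # single group covering all cells: mean z-score is ~0 per gene
  one <- groupProfiles(sce, stats::setNames(rep("all", 200),
                                            colnames(sce)), tps)
  expect_lt(max(abs(one)), 1e-10)

  expect_error(groupProfiles(sce, labs, tps, minorGroupFraction = 0.9),
               "below the cell threshold")
})

test_that("regulon tables validate and round-trip", {
  df <- data.frame(tf = rep(c("tf1", "tf2"), c(6, 2)),
                   target = c(paste0("g", 1:6), paste0("h", 1:2)))
  expect_warning(regs <- readRegulons(df), "fewer than")
  expect_equal(names(regs), "tf1")
  expect_equal(length(regs$tf1), 6L)
  expect_error(readRegulons(data.frame(tf = "a",
                                       target = c("a", "b", "c", "d", "e"))),
               "own target")
})
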