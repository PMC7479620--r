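test_that("cumulative curves accumulate read fractions correctly", {
  expect_equal(cumulativeCurve(c(A = 100, B = 100))$cumFraction, c(0.5, 1))
  cv <- cumulativeCurve(c(A = 300, B = 100))
  expect_equal(cv$cumFraction, c(0.75, 1))
  expect_equal(cv$barcode, c("A", "B"))

  reads <- stats::setNames(rpois(1000, 50), sprintf("b%04d", 1:1000))
  cv2 <- cumulativeCurve(reads)
  expect_equal(cv2$cumFraction[1000], 1)
  expect_true(all(diff(cv2$cumFraction) >= 0))
  expect_true(all(diff(cv2$reads) <= 0))

  expect_error(cumulativeCurve(c(A = 5)), "two barcodes")
  expect_error(cumulativeCurve(c(A = 0, B = 0)), "zero")
})

test_that("the knee sits at the maximal perpendicular distance", {
  reads <- c(rep(10000, 50), rep(10, 500))
  names(reads) <- sprintf("b%03d", seq_along(reads))
  cv <- cumulativeCurve(reads)
  knee <- detectKnee(cv)
  # exhaustive evaluation of the above-chord distance over all ranks
  x <- log10(cv$rank); y <- cv$cumFraction; n <- length(x)
  chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  d <- (y - chord) * (x[n] - x[1]) /
    sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  expect_equal(knee$rank, which.max(d))
  expect_equal(knee$rank, 50)
  expect_equal(knee$threshold, 10000)

  expect_error(detectKnee(cumulativeCurve(c(A = 10, B = 5))), "knee")
  flat <- data.frame(rank = 1:4, reads = c(4, 3, 2, 1),
                     cumFraction = log10(1:4) / log10(4))
  expect_error(detectKnee(flat), "no knee")
})

test_that("knee selection separates cells from ambient barcodes", {
  ch <- smallCohort()
  totals <- Matrix::colSums(counts(ch$sce))
  knee <- detectKnee(cumulativeCurve(totals))
  selected <- names(totals)[totals >= knee$threshold]
  truthReal <- names(ambientFlag(ch$truth))[!ambientFlag(ch$truth)]
  precision <- mean(selected %in% truthReal)
  recall <- mean(truthReal %in% selected)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("cell filters apply sequentially with conserved accounting", {
  # 6 cells x 60 genes, one library; hand-crafted failure modes
  set.seed(1)
  m <- matrix(rpois(60 * 6, 5), 60, 6)
  m[, 1] <- 0; m[1:3, 1] <- 1          # low depth -> knee/min-reads
  m[, 2] <- c(rep(1, 10), rep(0, 50))  # 10 detected genes -> gene bounds
  m[, 3] <- 60                          # huge total -> UMI outlier
  m[, 4] <- 4; m[1:2, 4] <- c(40, 40)  # mito-heavy
  rn <- sprintf("g%03d", 1:60); rn[1:2] <- c("mt:a", "mt:b")
  sce <- makeSce(m)
  rownames(sce) <- rn
  thr <- qcThresholds(minReads = 10, geneLower = 20, geneUpper = 60,
                      umiSdMult = 1, mitoMaxFraction = 0.10,
                      mitoGenes = c("mt:a", "mt:b"))
  out <- qcFilterCells(sce, thr)
  rep <- out$report
  expect_equal(rep@nIn, 6L)
  expect_equal(as.integer(removedCounts(rep)["knee"]), 1L)
  expect_equal(as.integer(removedCounts(rep)["genes"]), 1L)
  expect_equal(as.integer(removedCounts(rep)["umi"]), 1L)
  expect_equal(as.integer(removedCounts(rep)["mito"]), 1L)
  expect_equal(nRetained(rep), 2L)
  expect_equal(rep@nIn, nRetained(rep) + sum(removedCounts(rep)))
})

test_that("zero-variance totals are never flagged as UMI outliers", {
  m <- matrix(5, nrow = 30, ncol = 3)  # three cells with identical totals
  sce <- makeSce(m)
  out <- qcFilterCells(sce, qcThresholds(minReads = 1, geneLower = 1,
                                         geneUpper = 100))
  expect_equal(as.integer(removedCounts(out$report)["umi"]), 0L)
  expect_equal(nRetained(out$report), 3L)
})

test_that("gene bounds are inclusive and mito fraction strict", {
  m <- matrix(0, nrow = 30, ncol = 3)
  m[1:10, 1] <- 10   # exactly geneLower detected genes
  m[, 2] <- 10       # exactly geneUpper (all 30 genes detected)
  m[, 3] <- 1; m[1, 3] <- 15   # mito cell: 15 mito of 44 total
  rownames(m) <- c("mt:a", sprintf("g%03d", 2:30))
  sce <- makeSce(m)
  out <- qcFilterCells(sce, qcThresholds(minReads = 1, geneLower = 10,
                                         geneUpper = 30, umiSdMult = 100,
                                         mitoMaxFraction = 0.10,
                                         mitoGenes = "mt:a"))
  expect_equal(colnames(out$sce), c("c001", "c002"))
  expect_equal(as.integer(removedCounts(out$report)["mito"]), 1L)
})

test_that("filtering is idempotent once the UMI rule is quiescent", {
  ch <- smallCohort()
  thr <- qcThresholds(minReads = 20, geneLower = 5, geneUpper = 5000)
  once <- qcFilterCells(ch$sce, thr)
  twice <- qcFilterCells(once$sce, thr)
  expect_lte(nRetained(twice$report), nRetained(once$report))
  if (removedCounts(twice$report)["umi"] == 0L &&
      removedCounts(once$report)["umi"] == 0L) {
    expect_identical(colnames(twice$sce), colnames(once$sce))
  }
})

test_that("an emptying filter step names itself", {
  m <- matrix(1, nrow = 20, ncol = 3)
  sce <- makeSce(m)
  expect_error(
    qcFilterCells(sce, qcThresholds(minReads = 1000, geneLower = 1,
                                    geneUpper = 100)),
    "minimum reads")
  expect_error(
    qcFilterCells(sce, qcThresholds(minReads = 1, geneLower = 21,
                                    geneUpper = 100)),
    "detected-gene")
})
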