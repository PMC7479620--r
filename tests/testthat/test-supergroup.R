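test_that("exclusion prunes the least-correlated group iteratively", {
  corr <- matrix(c(1, .99, .10,
                   .99, 1, .12,
                   .10, .12, 1), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sizes <- c(A = 50L, B = 40L, C = 30L)
  out <- excludeUncorrelated(corr, sizes, rMin = 0.90)
  expect_equal(out$excluded, "C")
  expect_setequal(out$retained, c("A", "B"))

  # loop never entered when everything correlates
  hi <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(hi) <- 1
  expect_equal(excludeUncorrelated(hi, c(a = 1L, b = 1L, c = 1L))$excluded,
               character(0))

  # two groups cannot shrink further
  lo <- matrix(c(1, .5, .5, 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_warning(res2 <- excludeUncorrelated(lo, c(x = 1L, y = 1L)),
                 "retained")
  expect_setequal(res2$retained, c("x", "y"))
  expect_error(excludeUncorrelated(lo[1, 1, drop = FALSE], c(x = 1L)),
               "two groups")
})

test_that("exclusion matches the naive oracle on random structures", {
  for (s in 1:30) {
    set.seed(s)
    k <- sample(3:6, 1)
    base <- matrix(rnorm(40 * k), 40, k)
    base <- base + rnorm(40) * sample(c(0, 3), 1)  # sometimes correlated
    corr <- cor(base)
    dimnames(corr) <- list(paste0("grp", 1:k), paste0("grp", 1:k))
    sizes <- stats::setNames(sample(10:60, k), colnames(corr))
    mine <- suppressWarnings(excludeUncorrelated(corr, sizes, 0.5))
    orac <- oracleExclude(corr, sizes, 0.5)
    expect_identical(mine$excluded, orac$excluded)
    expect_setequal(mine$retained, orac$retained)
    # terminal invariant
    if (length(mine$retained) > 2L) {
      off <- mine$corr[row(mine$corr) != col(mine$corr)]
      expect_gte(min(off), 0.5)
    }
  }
})

test_that("merging pools counts and stops below the threshold", {
  # duplicate groups merge at r = 1
  m <- cbind(c(5, 1, 3, 8), c(5, 1, 3, 8), c(50, 2, 1, 0))
  sce <- makeSce(m)
  labs <- stats::setNames(c("a", "b", "c"), colnames(sce))
  res <- mergeSupergroups(sce, labs, rownames(sce), rMerge = 0.95)
  expect_equal(unname(res$map[c("a", "b")]), c("a+b", "a+b"))
  expect_equal(unname(res$map["c"]), "c")
  # merged profile equals pooled counts, not averaged profiles
  expect_equal(unname(rawSums(res$profiles)[, "a+b"]), c(10, 2, 6, 16))

  # nothing merges below threshold
  m2 <- cbind(c(10, 0, 0, 1), c(0, 10, 1, 0), c(1, 0, 10, 3))
  sce2 <- makeSce(m2)
  labs2 <- stats::setNames(c("a", "b", "c"), colnames(sce2))
  res2 <- mergeSupergroups(sce2, labs2, rownames(sce2), rMerge = 0.95)
  expect_equal(sort(unique(res2$map)), c("a", "b", "c"))

  # single group returns itself
  res1 <- mergeSupergroups(sce[, 1, drop = FALSE],
                           labs[1], rownames(sce))
  expect_equal(unname(res1$map), "a")
})

test_that("merge order equals brute-force re-pooling agglomeration", {
  for (s in 1:20) {
    set.seed(100 + s)
    k <- sample(3:6, 1)
    nPer <- 15L
    centers <- matrix(rlnorm(30 * k, 2, 1), 30, k)
    # plant a near-duplicate pair to force at least one merge sometimes
    if (k >= 2) centers[, 2] <- centers[, 1] * rlnorm(30, 0, 0.05)
    cells <- matrix(0L, 30, k * nPer)
    labs <- character(k * nPer)
    for (g in seq_len(k)) {
      idx <- (g - 1) * nPer + seq_len(nPer)
      cells[, idx] <- rpois(30 * nPer, centers[, g])
      labs[idx] <- paste0("grp", g)
    }
    sce <- makeSce(cells)
    names(labs) <- colnames(sce)
    genes <- rownames(sce)
    mine <- mergeSupergroups(sce, labs, genes, rMerge = 0.95)
    orac <- oracleAgglomerate(counts(sce), labs, genes, rMerge = 0.95)
    expect_equal(length(mine$history), length(orac$history))
    for (i in seq_along(mine$history)) {
      expect_identical(mine$history[[i]], orac$history[[i]])
    }
    expect_setequal(unique(mine$map),
                    vapply(orac$groups, paste, character(1),
                           collapse = "+"))
    # final correlations all below the merge threshold
    if (!is.null(mine$corr)) {
      expect_lt(max(mine$corr[row(mine$corr) != col(mine$corr)]), 0.95)
    }
    # coarsening: each fine cluster maps to exactly one super-group
    expect_setequal(names(mine$map), unique(labs))
  }
})

test_that("group relabeling permutes but does not change the merges", {
  set.seed(77)
  m <- cbind(matrix(rpois(40 * 10, 5), 40),
             matrix(rpois(40 * 10, c(rep(5, 20), rep(25, 20))), 40))
  sce <- makeSce(m)
  labs <- stats::setNames(rep(c("a", "b", "c", "d"), each = 5),
                          colnames(sce))
  genes <- rownames(sce)
  res <- mergeSupergroups(sce, labs, genes, rMerge = 0.9)
  perm <- c(a = "w", b = "x", c = "y", d = "z")
  res2 <- mergeSupergroups(sce, stats::setNames(perm[labs], names(labs)),
                           genes, rMerge = 0.9)
  # partitions over cells are identical up to renaming
  part1 <- res$map[labs]
  part2 <- res2$map[perm[labs]]
  expect_equal(length(unique(part1)), length(unique(part2)))
  expect_true(all(table(part1, part2) %in%
                    c(0L, as.vector(table(part1)))))
})

test_that("library-dominated subclusters are flagged strictly", {
  labs <- stats::setNames(rep(c("g1", "g2"), each = 10),
                          sprintf("c%02d", 1:20))
  libs <- stats::setNames(c(rep("L1", 6), rep("L2", 4),   # g1: 60% L1
                            rep("L1", 5), rep("L2", 5)),  # g2: 50/50
                          names(labs))
  expect_equal(flagLibraryBiased(labs, libs, 0.5), "g1")

  # uniformly mixed cohort: no group flagged
  ch <- smallCohort()
  cells <- realCells(ch)
  fl <- flagLibraryBiased(cellSubtype(ch$truth)[cells],
                          stats::setNames(
                            as.character(colData(ch$sce)[cells, "library"]),
                            cells))
  expect_equal(fl, character(0))
})
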