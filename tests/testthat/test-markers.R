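test_that("rank-sum p-values match the enumeration oracle exactly", {
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 2 / 6)
  expect_equal(r$method, "exact")
  expect_equal(rankSumTest(5, c(1, 2, 3))$p.value,
               oracleWilcoxExact(5, c(1, 2, 3)))

  # all no-tie inputs with n_a + n_b <= 10, several draws each
  set.seed(31)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        vals <- sample(seq_len(50), na + nb)
        a <- vals[seq_len(na)]
        b <- vals[na + seq_len(nb)]
        expect_equal(rankSumTest(a, b)$p.value, oracleWilcoxExact(a, b),
                     info = sprintf("na=%d nb=%d", na, nb))
      }
    }
  }
})

test_that("degenerate and approximate branches behave as documented", {
  d <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$p.value, 1)

  # normal branch agrees with the reference implementation in stats
  set.seed(8)
  a <- rpois(30, 10)
  b <- rpois(40, 12)
  mine <- rankSumTest(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$method, "normal")
  expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(mine$statistic, unname(ref$statistic))
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p))
    expect_true(all(q >= p - 1e-12))
    # rejection set equals the textbook step-up rule at alpha = 0.1
    alpha <- 0.1
    ps <- sort(p)
    kmax <- suppressWarnings(max(which(ps <= seq_along(ps) /
                                         length(p) * alpha)))
    stepUp <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, length(p))
    expect_equal(q <= alpha + 1e-12, stepUp)
  }
})

test_that("planted markers are counted as DEGs, null data barely any", {
  set.seed(21)
  nPer <- 200L
  m <- matrix(rpois(300 * 2 * nPer, 5), 300)
  m[1:20, seq_len(nPer)] <- rpois(20 * nPer, 5 * 4)  # ~log2FC 2
  sce <- normalizeCounts(makeSce(m))
  labs <- stats::setNames(rep(c("A", "B"), each = nPer), colnames(sce))
  res <- degCount(sce, labs)
  expect_gte(res$count, 20L)
  expect_true(all(c("gene", "group", "p", "q", "log2fc") %in%
                    names(res$table)))
  expect_equal(degCount(sce, labs, qMax = 0)$count, 0L)

  # null: both groups from one distribution, 20 seeds
  nullCounts <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    m0 <- matrix(rpois(500 * 100, 3), 500)
    sce0 <- normalizeCounts(makeSce(m0))
    labs0 <- stats::setNames(rep(c("A", "B"), each = 50), colnames(sce0))
    degCount(sce0, labs0)$count
  }, integer(1))
  expect_lte(mean(nullCounts), 5 * 0.05 * 500)
})

test_that("tiny super-groups are dropped from testing with a warning", {
  set.seed(3)
  m <- matrix(rpois(50 * 20, 5), 50)
  sce <- normalizeCounts(makeSce(m))
  labs <- stats::setNames(c(rep("A", 9), rep("B", 9), rep("C", 2)),
                          colnames(sce))
  expect_warning(res <- degCount(sce, labs), "fewer than 3")
  expect_false("C" %in% res$table$group)
  labs2 <- stats::setNames(c(rep("A", 18), rep("C", 2)), colnames(sce))
  expect_warning(expect_error(degCount(sce, labs2), "two testable"))
})

test_that("proportion tables report shares, normalized counts, ratios", {
  labs <- stats::setNames(rep(c("X", "Y"), times = c(10, 10)),
                          sprintf("c%02d", 1:20))
  cond <- stats::setNames(rep("only", 20), names(labs))
  pt <- proportionTable(labs, cond)
  expect_equal(pt$byCondition$share, c(0.5, 0.5))
  expect_null(pt$ratio)

  labs2 <- stats::setNames(rep(c("X", "Y", "X", "Y"),
                               times = c(80, 20, 40, 60)),
                           sprintf("c%03d", 1:200))
  cond2 <- stats::setNames(rep(c("A", "B"), each = 100), names(labs2))
  pt2 <- proportionTable(labs2, cond2)
  expect_equal(pt2$ratio$ratio[pt2$ratio$group == "X"], 2.0)
  byC <- pt2$byCondition
  for (cn in c("A", "B")) {
    expect_equal(sum(byC$share[byC$condition == cn]), 1)
  }
  # normalized counts rescale condition B to condition A's size
  expect_equal(byC$normalizedCount[byC$condition == "B"],
               c(40, 60))

  # absent group: undefined ratio, flagged
  labs3 <- stats::setNames(c(rep(c("X", "Y"), each = 5), rep("X", 10)),
                           sprintf("c%03d", 1:20))
  cond3 <- stats::setNames(rep(c("A", "B"), each = 10), names(labs3))
  pt3 <- proportionTable(labs3, cond3)
  yRow <- pt3$ratio[pt3$ratio$group == "Y", ]
  expect_false(yRow$defined)
  expect_true(is.na(yRow$ratio))
})
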