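#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Uses the exact null distribution of the Mann-Whitney U statistic when
#' the combined sample size is at most 20 and the data carry no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction.  When every value in both samples is identical
#' the test is degenerate and `p = 1` is returned with a flag.
#'
#' @param a,b non-empty numeric vectors.
#' @return a list with `statistic` (the U statistic of `a`), `p.value`,
#'   `method` (`"exact"` or `"normal"`), and `degenerate`.
#' @export
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))$p.value  # 2/6
rankSumTest <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("NA values are not allowed", call. = FALSE)
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L ||
      (na == nb && all(sort(a) == sort(b)))) {
    return(list(statistic = na * nb / 2, p.value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (na + nb <= 20L && !ties) {
    if (u > na * nb / 2) {
      p <- 2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(u, na, nb)
    }
    p <- min(p, 1)
    method <- "exact"
  } else {
    n <- na + nb
    tieTab <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(list(statistic = u, p.value = 1, method = "degenerate",
                  degenerate = TRUE))
    }
    z <- u - na * nb / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = u, p.value = p, method = method, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, in the input order.
#' @export
bhAdjust <- function(pValues) {
  if (anyNA(pValues) || any(pValues < 0) || any(pValues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pValues, method = "BH")
}

# Vectorized one-vs-rest rank-sum across the rows of a dense matrix.
# Ranks and tie corrections depend only on the values, not the grouping,
# so they are computed once and reused for every group.
.rankSumByGroup <- function(X, labels) {
  n <- ncol(X)
  R <- t(apply(X, 1L, rank))
  tieCorr <- apply(X, 1L, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })
  groups <- sort(unique(labels))
  out <- lapply(groups, function(g) {
    inG <- labels == g
    n1 <- sum(inG)
    n2 <- n - n1
    u <- rowSums(R[, inG, drop = FALSE]) - n1 * (n1 + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieCorr / (n * (n - 1)))
    z <- u - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, 0))
    p <- 2 * stats::pnorm(-abs(z))
    p[sigma2 <= 0] <- 1
    list(group = g, statistic = u, p = p)
  })
  names(out) <- groups
  out
}

#' Count differentially expressed genes among super-groups
#'
#' One-vs-rest Wilcoxon rank-sum tests per gene per super-group over
#' genes detected in at least `minCellsDetected` cells, Benjamini-
#' Hochberg adjustment within each comparison, and a count of the unique
#' genes significant (`q < qMax`, `|log2FC| >= lfcMin`) in at least one
#' comparison.  Fold changes are computed on `expm1`-back-transformed
#' group means with a pseudocount of 1.  Super-groups with fewer than
#' three cells are excluded from testing with a warning.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay.
#' @param labels super-group label per cell.
#' @param qMax BH-adjusted significance threshold (default 0.05).
#' @param lfcMin minimal absolute log2 fold change (default 0.25).
#' @param minCellsDetected detection floor for testable genes
#'   (default 3).
#' @return a list with `count` (unique significant genes) and `table`
#'   (per gene per comparison: statistic, `p`, `q`, `log2fc`, `pctIn`,
#'   `pctOut`).
#' @export
degCount <- function(sce, labels, qMax = 0.05, lfcMin = 0.25,
                     minCellsDetected = 3L) {
  lc <- .logcounts(sce)
  labels <- .alignLabels(labels, colnames(lc), "super-group labels")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3L]
  if (length(small) > 0L) {
    warning(sprintf("super-group(s) %s have fewer than 3 cells; excluded",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(labels %in% small)
    lc <- lc[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) {
    stop("at least two testable super-groups are required", call. = FALSE)
  }
  detected <- Matrix::rowSums(lc > 0) >= minCellsDetected
  if (!any(detected)) {
    return(list(count = 0L,
                table = data.frame(gene = character(0),
                                   group = character(0))))
  }
  X <- as.matrix(lc[detected, , drop = FALSE])
  tests <- .rankSumByGroup(X, labels)
  E <- expm1(X)
  rows <- lapply(tests, function(tst) {
    inG <- labels == tst$group
    m1 <- rowMeans(E[, inG, drop = FALSE])
    m2 <- rowMeans(E[, !inG, drop = FALSE])
    data.frame(gene = rownames(X), group = tst$group,
               statistic = tst$statistic, p = tst$p,
               q = bhAdjust(tst$p),
               log2fc = log2((m1 + 1) / (m2 + 1)),
               pctIn = rowMeans(X[, inG, drop = FALSE] > 0),
               pctOut = rowMeans(X[, !inG, drop = FALSE] > 0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$q < qMax & abs(tab$log2fc) >= lfcMin
  list(count = length(unique(tab$gene[sig])), table = tab)
}

#' Group proportions and normalized counts across conditions
#'
#' For every condition, the share of each group among that condition's
#' cells and a count normalized to the size of the first condition.  With
#' exactly two conditions the proportional ratio (share in the first
#' condition over share in the second) is also reported; a zero share in
#' the denominator yields an undefined (`NA`) ratio rather than infinity.
#'
#' @param labels group label per cell.
#' @param condition condition label per cell (same cells).
#' @return a list with `byCondition` (`group`, `condition`, `count`,
#'   `share`, `normalizedCount`) and `ratio` (two-condition input only:
#'   `group`, `ratio`, `defined`; otherwise `NULL`).
#' @export
proportionTable <- function(labels, condition) {
  cells <- names(labels)
  if (is.null(cells)) cells <- as.character(seq_along(labels))
  labels <- .alignLabels(labels, cells, "group labels")
  condition <- .alignLabels(condition, cells, "condition labels")
  conds <- unique(condition)
  groups <- sort(unique(labels))
  counts <- table(factor(labels, groups), factor(condition, conds))
  condTotals <- colSums(counts)
  if (any(condTotals == 0)) stop("empty condition", call. = FALSE)
  refTotal <- condTotals[1L]
  long <- do.call(rbind, lapply(conds, function(cn) {
    data.frame(group = groups, condition = cn,
               count = as.integer(counts[, cn]),
               share = as.numeric(counts[, cn] / condTotals[cn]),
               normalizedCount =
                 as.numeric(counts[, cn] / condTotals[cn] * refTotal),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  ratio <- NULL
  if (length(conds) == 2L) {
    sA <- counts[, 1L] / condTotals[1L]
    sB <- counts[, 2L] / condTotals[2L]
    ratio <- data.frame(group = groups,
                        ratio = ifelse(sB > 0, sA / sB, NA_real_),
                        defined = sB > 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(byCondition = long, ratio = ratio)
}
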