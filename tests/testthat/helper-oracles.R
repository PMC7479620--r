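# Independent oracles, written naively and without package internals, so
# the implementation can be checked against a second route.

# Pearson correlation straight from the definition
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
oracleWilcoxExact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# Benjamini-Hochberg step-up, by hand
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  qSorted <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) {
    qSorted[i] <- min(qSorted[i:m])
  }
  q[ord] <- pmin(qSorted, 1)
  q
}

# log1p-CPM of per-group pooled counts, naive loops
oracleGroupLogCpm <- function(counts, labels, groups) {
  out <- sapply(groups, function(memberSet) {
    cells <- names(labels)[labels %in% memberSet]
    s <- rowSums(as.matrix(counts[, cells, drop = FALSE]))
    log1p(s / sum(s) * 1e6)
  })
  colnames(out) <- vapply(groups, function(g) paste(sort(g), collapse = "+"),
                          character(1))
  out
}

# Brute-force agglomeration: re-pool counts at every step, merge the
# most-correlated pair (>= rMerge) with first-in-label-order tie-break.
# Returns the member sets of the final super-groups and the merge order.
oracleAgglomerate <- function(counts, labels, genes, rMerge = 0.95) {
  groups <- lapply(sort(unique(labels)), function(g) g)
  history <- list()
  repeat {
    if (length(groups) < 2L) break
    lcpm <- oracleGroupLogCpm(counts, labels, groups)[genes, , drop = FALSE]
    k <- length(groups)
    best <- NULL
    bestR <- -Inf
    nm <- colnames(lcpm)
    for (i in order(nm)) {
      for (j in order(nm)) {
        if (nm[j] <= nm[i]) next
        r <- oraclePearson(lcpm[, i], lcpm[, j])
        if (r > bestR + 1e-12) {
          bestR <- r
          best <- c(i, j)
        }
      }
    }
    if (bestR < rMerge) break
    history[[length(history) + 1L]] <-
      list(a = sort(groups[[best[1L]]]), b = sort(groups[[best[2L]]]))
    merged <- sort(c(groups[[best[1L]]], groups[[best[2L]]]))
    groups <- c(groups[-best], list(merged))
  }
  list(groups = lapply(groups, sort), history = history)
}

# Iterative exclusion: drop the group with smallest mean off-diagonal
# correlation while the minimum is below rMin and > 2 groups remain.
oracleExclude <- function(corr, sizes, rMin = 0.90) {
  excluded <- character(0)
  repeat {
    k <- ncol(corr)
    off <- corr[row(corr) != col(corr)]
    if (k <= 2L || min(off) >= rMin) break
    meanOff <- (rowSums(corr) - 1) / (k - 1)
    cand <- names(meanOff)[meanOff == min(meanOff)]
    if (length(cand) > 1L) {
      sz <- sizes[cand]
      cand <- cand[sz == min(sz)]
      cand <- sort(cand)[1L]
    }
    excluded <- c(excluded, cand)
    keep <- setdiff(colnames(corr), cand)
    corr <- corr[keep, keep, drop = FALSE]
  }
  list(retained = colnames(corr), excluded = excluded)
}
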