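# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the session RNG.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.counts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

.logcounts <- function(x) {
  if (!is(x, "SummarizedExperiment") ||
      !"logcounts" %in% SummarizedExperiment::assayNames(x)) {
    stop("a 'logcounts' assay is required; run normalizeCounts() first",
         call. = FALSE)
  }
  SummarizedExperiment::assay(x, "logcounts")
}

# row-wise mean and variance that stay sparse-aware
.rowStats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0
  list(mean = as.numeric(mu), var = as.numeric(v))
}

.offdiag <- function(m) m[row(m) != col(m)]

# labels coerced to a character vector aligned with (and named by) `cells`
.alignLabels <- function(labels, cells, what = "labels") {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    miss <- setdiff(cells, names(labels))
    if (length(miss) > 0L) {
      stop(sprintf("%s missing for %d cell(s), e.g. '%s'", what,
                   length(miss), miss[1L]), call. = FALSE)
    }
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop(sprintf("unnamed %s must have one entry per cell", what),
         call. = FALSE)
  } else {
    names(labels) <- cells
  }
  if (anyNA(labels)) {
    stop(sprintf("%s contain NA", what), call. = FALSE)
  }
  labels
}

# One-sided (greater) Mann-Whitney with midranks, tie-corrected normal
# approximation and continuity correction; degenerate inputs give p = 1.
.ranksumGreater <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(1)
  }
  z <- (u - nx * ny / 2 - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}
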