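# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stage-keyed seed derivation: all randomness flows from one master seed, but
# each pipeline stage gets its own reproducible stream.
stageSeed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# Spearman correlation with asymptotic two-sided p, available-case.
# Ties use average ranks throughout the package.
spearmanTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
}

# Accept a plain genes x samples matrix or a SummarizedExperiment (assay 1).
exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) stop("expression matrix needs gene rownames")
  if (is.null(colnames(x))) stop("expression matrix needs sample colnames")
  x
}

# Per-gene z-scores across cohort samples (moment-based, available-case).
zscoreGenes <- function(expr) {
  mu <- rowMeans(expr, na.rm = TRUE)
  sdv <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- NA_real_
  (expr - mu) / sdv
}

# Inclusive-at-cutoff quantile convention (linear-interpolation quantiles).
quantileCut <- function(x, p) stats::quantile(x, p, na.rm = TRUE, type = 7)
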