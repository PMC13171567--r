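#' Derive a gene signature from per-fold linear coefficients
#'
#' Coefficients are averaged across folds; a gene's sign-stability is the
#' fraction of folds whose coefficient sign agrees with the sign of the mean
#' (a zero fold coefficient never agrees). The up (down) set is the top
#' `nTop` genes by |mean weight| among genes with positive (negative) mean
#' weight meeting the stability threshold.
#'
#' @param foldCoefs genes x folds coefficient matrix (>= 2 folds), e.g. from
#'   [foldCoefficients()].
#' @param nTop genes selected per direction (default 25).
#' @param stabilityMin minimum sign-stability fraction (default 0.8).
#' @return a [SignatureModel-class].
#' @examples
#' cf <- cbind(f1 = c(gA = 1, gB = -1, gC = 0.2),
#'             f2 = c(gA = 0.8, gB = -1.2, gC = 0.1))
#' deriveSignature(cf, nTop = 2, stabilityMin = 0.5)
#' @export
deriveSignature <- function(foldCoefs, nTop = 25L, stabilityMin = 0.8) {
  foldCoefs <- as.matrix(foldCoefs)
  if (ncol(foldCoefs) < 2L) stop("need coefficients from at least 2 folds")
  if (is.null(rownames(foldCoefs))) stop("foldCoefs needs gene rownames")
  meanW <- rowMeans(foldCoefs)
  stab <- vapply(seq_len(nrow(foldCoefs)), function(g) {
    if (meanW[g] == 0) return(0)
    mean(sign(foldCoefs[g, ]) == sign(meanW[g]))
  }, numeric(1))
  names(stab) <- rownames(foldCoefs)
  pass <- stab >= stabilityMin
  if (!any(pass))
    stop("no gene passes the sign-stability threshold (",
         stabilityMin, "); consider lowering it")
  pick <- function(dir) {
    idx <- which(pass & sign(meanW) == dir)
    idx <- idx[order(-abs(meanW[idx]), rownames(foldCoefs)[idx])]
    rownames(foldCoefs)[utils::head(idx, nTop)]
  }
  new("SignatureModel", meanWeight = meanW, foldWeights = foldCoefs,
      stability = stab, upGenes = pick(1), downGenes = pick(-1),
      nTop = as.integer(nTop), stabilityMin = stabilityMin)
}

availableSets <- function(expr, up, down, requireBoth = FALSE) {
  up <- intersect(up, rownames(expr))
  down <- intersect(down, rownames(expr))
  if (length(up) + length(down) == 0L)
    stop("no signature genes present in the cohort")
  if (requireBoth && (length(up) == 0L || length(down) == 0L))
    stop("both up and down sets must intersect the cohort genes")
  list(up = up, down = down)
}

#' Directional up-down signature score
#'
#' Genes are z-scored across cohort samples (moment-based); a sample's score
#' is the mean z over available up genes minus the mean z over available
#' down genes. Available-case: genes absent from the cohort are dropped and
#' the per-sample count of genes used is recorded.
#'
#' @param expr cohort genes x samples matrix (or SummarizedExperiment).
#' @param sig a [SignatureModel-class] (>= 1 up or down gene present).
#' @return a [SignatureScoreTable-class] with method "updown".
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 20, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' sig <- new("SignatureModel",
#'   meanWeight = c(SIG001 = 1, SIG002 = -1),
#'   foldWeights = cbind(c(1, -1), c(1, -1)),
#'   stability = c(SIG001 = 1, SIG002 = 1),
#'   upGenes = "SIG001", downGenes = "SIG002",
#'   nTop = 1L, stabilityMin = 0.8)
#' updownScore(coh$expression, sig)
#' @export
updownScore <- function(expr, sig) {
  expr <- exprMatrix(expr)
  stopifnot(is(sig, "SignatureModel"))
  sets <- availableSets(expr, sig@upGenes, sig@downGenes)
  z <- zscoreGenes(expr)
  meanSet <- function(genes) {
    if (length(genes) == 0L) rep(0, ncol(expr))
    else colMeans(z[genes, , drop = FALSE], na.rm = TRUE)
  }
  score <- meanSet(sets$up) - meanSet(sets$down)
  nUsed <- colSums(!is.na(z[c(sets$up, sets$down), , drop = FALSE]))
  new("SignatureScoreTable", sample = colnames(expr),
      score = unname(score), method = "updown",
      nGenesUsed = as.integer(nUsed),
      params = list(nUp = length(sets$up), nDown = length(sets$down)))
}

# Integrated running-sum enrichment for one sample's expression vector.
# Genes are walked in decreasing expression order; at each position the
# cumulative normalized in-set weight (weight = ascending-rank^alpha, so the
# top-ranked gene is weighted most) is compared with the cumulative uniform
# fraction of out-of-set genes, and the differences are summed.
ssgseaES <- function(x, inSet, alpha) {
  G <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  inS <- names(x) %in% inSet
  nOut <- G - sum(inS)
  if (nOut == 0L) stop("gene set equals the expression universe")
  w <- r^alpha
  wOrd <- w[ord] * inS[ord]
  cumIn <- cumsum(wOrd) / sum(wOrd)
  cumOut <- cumsum(!inS[ord]) / nOut
  sum(cumIn - cumOut)
}

#' Single-sample gene-set enrichment (ssGSEA) signature score
#'
#' Classical single-sample enrichment: per sample, genes are ranked by
#' expression; walking the ranking from the top, the enrichment score is the
#' integrated difference between the cumulative normalized weight of in-set
#' genes (weight = ascending rank^alpha) and the cumulative uniform fraction
#' of out-of-set genes. The directional score is ES(up) - ES(down). Being
#' rank-based, it is invariant to any strictly monotone per-sample transform
#' of expression, which is what makes it portable across platforms.
#'
#' @param expr cohort genes x samples matrix.
#' @param upGenes,downGenes gene sets (either may be empty, not both; each
#'   non-empty set must intersect the cohort genes and must not equal the
#'   whole universe).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize if TRUE, divide all scores by (max - min) across the
#'   cohort (default FALSE).
#' @return a [SignatureScoreTable-class] with method "ssgsea".
#' @examples
#' expr <- matrix(c(3, 2, 1), 3, 1,
#'                dimnames = list(c("gA", "gB", "gC"), "s1"))
#' ssgseaScore(expr, upGenes = "gA", downGenes = character(0),
#'             alpha = 0)@score  # 1.5
#' @export
ssgseaScore <- function(expr, upGenes, downGenes = character(0),
                        alpha = 0.25, normalize = FALSE) {
  expr <- exprMatrix(expr)
  up <- intersect(upGenes, rownames(expr))
  down <- intersect(downGenes, rownames(expr))
  if (length(upGenes) && !length(up))
    stop("up set does not intersect the cohort genes")
  if (length(downGenes) && !length(down))
    stop("down set does not intersect the cohort genes")
  if (!length(up) && !length(down)) stop("both gene sets are empty")
  score <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    names(x) <- rownames(expr)
    x <- x[!is.na(x)]
    esUp <- if (length(up)) ssgseaES(x, up, alpha) else 0
    esDown <- if (length(down)) ssgseaES(x, down, alpha) else 0
    esUp - esDown
  }, numeric(1))
  if (normalize) {
    rng <- max(score) - min(score)
    if (rng > 0) score <- score / rng
  }
  nUsed <- colSums(!is.na(expr[c(up, down), , drop = FALSE]))
  new("SignatureScoreTable", sample = colnames(expr), score = unname(score),
      method = "ssgsea",
      nGenesUsed = as.integer(nUsed),
      params = list(alpha = alpha, normalize = normalize,
                    nUp = length(up), nDown = length(down)))
}

#' Rank-based signature score
#'
#' Per sample, genes are given ascending ranks 1..G over available genes;
#' the score is (mean rank of up genes - mean rank of down genes) / G,
#' bounded in (-1, 1) and invariant to monotone per-sample transforms.
#'
#' @param expr cohort genes x samples matrix.
#' @param sig a [SignatureModel-class].
#' @return a [SignatureScoreTable-class] with method "rank".
#' @examples
#' expr <- matrix(4:1, 4, 1,
#'                dimnames = list(c("top", "b", "c", "bottom"), "s1"))
#' sig <- new("SignatureModel", meanWeight = c(top = 1, bottom = -1),
#'   foldWeights = cbind(c(1, -1), c(1, -1)),
#'   stability = c(top = 1, bottom = 1),
#'   upGenes = "top", downGenes = "bottom", nTop = 1L, stabilityMin = 0.8)
#' rankScore(expr, sig)@score  # 0.75
#' @export
rankScore <- function(expr, sig) {
  expr <- exprMatrix(expr)
  stopifnot(is(sig, "SignatureModel"))
  sets <- availableSets(expr, sig@upGenes, sig@downGenes)
  score <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    names(x) <- rownames(expr)
    x <- x[!is.na(x)]
    G <- length(x)
    r <- rank(x, ties.method = "average")
    mUp <- if (length(sets$up)) mean(r[intersect(sets$up, names(x))]) else 0
    mDown <- if (length(sets$down))
      mean(r[intersect(sets$down, names(x))]) else 0
    (mUp - mDown) / G
  }, numeric(1))
  nUsed <- colSums(!is.na(expr[c(sets$up, sets$down), , drop = FALSE]))
  new("SignatureScoreTable", sample = colnames(expr), score = unname(score),
      method = "rank", nGenesUsed = as.integer(nUsed),
      params = list(nUp = length(sets$up), nDown = length(sets$down)))
}

#' Derive a compact elastic-net gene panel
#'
#' Fits an elastic net under the same leakage-safe tuning harness (group-aware
#' inner selection of mixing and penalty), refits on the full data with the
#' tuned hyperparameters, and keeps the top `size` genes by absolute
#' coefficient; ties break lexicographically by gene id for determinism.
#' Fewer nonzero coefficients than `size` yields a shorter panel with a
#' warning.
#'
#' @param expr genes x samples matrix.
#' @param y named outcome vector.
#' @param size panel size (default 15).
#' @param K group-aware folds used for tuning (default 5).
#' @param seed integer seed.
#' @param spec an elastic-net [ModelSpec-class] (grid is config-exposed).
#' @return a [ReducedPanel-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 60, nSignatureGenes = 8, seed = 9))
#' z <- standardizeAndOrient(sim$responses)
#' y <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 10)))@weightedScore
#' deriveReducedPanel(sim$expression, y, size = 10, K = 3, seed = 1)
#' @export
deriveReducedPanel <- function(expr, y, size = 15L, K = 5L, seed = 1L,
                               spec = modelSpec("elastic_net")) {
  expr <- exprMatrix(expr)
  if (size < 1L) stop("size must be at least 1")
  if (spec@family != "elastic_net") stop("panel derivation uses elastic net")
  samples <- names(y)
  X <- t(expr[, samples, drop = FALSE])
  params <- tuneInner(X, y, samples, spec, stageSeed(seed, "panel-tune"))
  sc <- scaleTrain(X)
  Xs <- applyScale(X, sc)
  lambdaPath <- sort(spec@grid$lambda, decreasing = TRUE)
  fit <- fitCandidate("elastic_net", Xs, y,
                      list(alpha = params$alpha, lambdaPath = lambdaPath),
                      seed)
  cf <- coefCandidate("elastic_net", fit, list(lambda = params$lambda),
                      sc$genes)
  nz <- cf[cf != 0]
  if (length(nz) < size)
    warning("only ", length(nz), " nonzero coefficients; panel is shorter ",
            "than the requested ", size)
  ord <- order(-abs(nz), names(nz))
  sel <- utils::head(ord, size)
  new("ReducedPanel", genes = names(nz)[sel], weights = unname(nz[sel]),
      provenance = list(alpha = params$alpha, lambda = params$lambda,
                        size = as.integer(size), seed = as.integer(seed)))
}

#' Concordance between two signature score tables
#'
#' Spearman correlation (asymptotic two-sided p) over the samples shared by
#' the two tables; errors with fewer than 3 shared samples.
#'
#' @param a,b [SignatureScoreTable-class] objects.
#' @return list with `rho`, `p`, `n`.
#' @examples
#' s1 <- new("SignatureScoreTable", sample = paste0("s", 1:5),
#'           score = c(1, 2, 3, 4, 5), method = "updown",
#'           nGenesUsed = rep(2L, 5), params = list())
#' s2 <- new("SignatureScoreTable", sample = paste0("s", 1:5),
#'           score = c(2, 1, 3, 5, 4), method = "rank",
#'           nGenesUsed = rep(2L, 5), params = list())
#' scoreConcordance(s1, s2)
#' @export
scoreConcordance <- function(a, b) {
  stopifnot(is(a, "SignatureScoreTable"), is(b, "SignatureScoreTable"))
  shared <- intersect(a@sample, b@sample)
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  sa <- stats::setNames(a@score, a@sample)[shared]
  sb <- stats::setNames(b@score, b@sample)[shared]
  spearmanTest(sa, sb)
}

#' Score a cohort with a reduced panel
#'
#' Weighted sum of per-gene cohort z-scores using the panel's elastic-net
#' coefficients (available-case over panel genes present in the cohort).
#'
#' @param expr cohort genes x samples matrix.
#' @param panel a [ReducedPanel-class].
#' @return a [SignatureScoreTable-class] with method "panel".
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 20, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' panel <- new("ReducedPanel", genes = c("SIG001", "SIG002"),
#'              weights = c(0.5, -0.5), provenance = list())
#' panelScore(coh$expression, panel)
#' @export
panelScore <- function(expr, panel) {
  expr <- exprMatrix(expr)
  stopifnot(is(panel, "ReducedPanel"))
  present <- panel@genes %in% rownames(expr)
  if (!any(present)) stop("no panel genes present in the cohort")
  genes <- panel@genes[present]
  w <- panel@weights[present]
  z <- zscoreGenes(expr)[genes, , drop = FALSE]
  z[is.na(z)] <- 0
  score <- as.numeric(crossprod(z, w))
  new("SignatureScoreTable", sample = colnames(expr), score = score,
      method = "panel", nGenesUsed = rep(length(genes), ncol(expr)),
      params = list(size = length(genes)))
}
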