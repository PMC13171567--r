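#' Signature-score correlations with named axis genes
#'
#' Available-case Spearman correlation (asymptotic two-sided p) between a
#' projected signature score and each named axis gene's expression; genes
#' absent from the cohort get a status row rather than an error. No
#' multiple-testing adjustment is applied across this small named set.
#'
#' @param scores a [SignatureScoreTable-class].
#' @param expr cohort genes x samples matrix.
#' @param axisGenes character vector of gene ids to test.
#' @return data.frame: gene, rho, p, n, status ("ok" / "absent" /
#'   "insufficient n").
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 30, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' sc <- new("SignatureScoreTable", sample = colnames(coh$expression),
#'           score = coh$truth@cohortLatent, method = "updown",
#'           nGenesUsed = rep(1L, 30), params = list())
#' axisCorrelations(sc, coh$expression, c("FGFR1", "KLB", "MISSING"))
#' @export
axisCorrelations <- function(scores, expr, axisGenes) {
  stopifnot(is(scores, "SignatureScoreTable"))
  expr <- exprMatrix(expr)
  s <- stats::setNames(scores@score, scores@sample)
  do.call(rbind, lapply(axisGenes, function(g) {
    if (!g %in% rownames(expr))
      return(data.frame(gene = g, rho = NA_real_, p = NA_real_, n = 0L,
                        status = "absent"))
    shared <- intersect(names(s), colnames(expr))
    x <- expr[g, shared]
    ok <- !is.na(x) & !is.na(s[shared])
    if (sum(ok) < 3L)
      return(data.frame(gene = g, rho = NA_real_, p = NA_real_,
                        n = sum(ok), status = "insufficient n"))
    st <- spearmanTest(s[shared], x)
    data.frame(gene = g, rho = st$rho, p = st$p, n = st$n, status = "ok")
  }))
}

#' Compare signature scores between marker-high and marker-low samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test between the score
#' distributions of samples at or above the upper quantile of a gene's
#' expression versus at or below the lower quantile (cutoffs inclusive;
#' middle samples excluded). Exact p for small tie-free groups.
#'
#' @param scores a [SignatureScoreTable-class].
#' @param expr cohort genes x samples matrix.
#' @param gene gene id defining the strata.
#' @param qHi,qLo quantile cutoffs (defaults 0.75 / 0.25).
#' @return list: statistic (U for the high group), p, nHigh, nLow.
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40), 2, 20,
#'                dimnames = list(c("FGFR1", "KLB"), paste0("s", 1:20)))
#' sc <- new("SignatureScoreTable", sample = paste0("s", 1:20),
#'           score = -expr["FGFR1", ], method = "updown",
#'           nGenesUsed = rep(1L, 20), params = list())
#' groupCompare(sc, expr, "FGFR1")
#' @export
groupCompare <- function(scores, expr, gene, qHi = 0.75, qLo = 0.25) {
  stopifnot(is(scores, "SignatureScoreTable"))
  expr <- exprMatrix(expr)
  if (!gene %in% rownames(expr)) stop("gene absent from cohort: ", gene)
  s <- stats::setNames(scores@score, scores@sample)
  shared <- intersect(names(s), colnames(expr))
  x <- expr[gene, shared]
  hi <- shared[x >= quantileCut(x, qHi)]
  lo <- shared[x <= quantileCut(x, qLo)]
  if (!length(hi) || !length(lo))
    stop("empty stratum at quantiles ", qLo, "/", qHi)
  wt <- suppressWarnings(stats::wilcox.test(s[hi], s[lo],
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       nHigh = length(hi), nLow = length(lo))
}

#' Transcriptome-wide gene-signature association
#'
#' Spearman correlation of every cohort gene with the signature score
#' (available-case n per gene), with Benjamini-Hochberg adjustment across all
#' tested genes.
#'
#' @param scores a [SignatureScoreTable-class].
#' @param expr cohort genes x samples matrix.
#' @param fdrQ FDR threshold annotated in the output (default 0.05).
#' @return data.frame: gene, rho, p, q, n, significant; ordered by p.
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 30,
#'                         nSignatureGenes = 5, cohortNSamples = 30, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' sc <- new("SignatureScoreTable", sample = colnames(coh$expression),
#'           score = coh$truth@cohortLatent, method = "updown",
#'           nGenesUsed = rep(1L, 30), params = list())
#' head(genewideAssociation(sc, coh$expression))
#' @export
genewideAssociation <- function(scores, expr, fdrQ = 0.05) {
  stopifnot(is(scores, "SignatureScoreTable"))
  expr <- exprMatrix(expr)
  s <- stats::setNames(scores@score, scores@sample)
  shared <- intersect(names(s), colnames(expr))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  res <- do.call(rbind, lapply(rownames(expr), function(g) {
    st <- spearmanTest(s[shared], expr[g, shared])
    data.frame(gene = g, rho = st$rho, p = st$p, n = st$n)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$q) & res$q <= fdrQ
  res[order(res$p), ]
}

# Rank-based AUC of `score` for positives vs negatives; satisfies the
# Mann-Whitney identity AUC = U / (nPos * nNeg) exactly (ties count 1/2).
rankAUC <- function(score, positive) {
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

rocPoints <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               tpr = mean(score[positive] >= t),
               fpr = mean(score[!positive] >= t))
  }))
}

#' Extreme-group ROC of a score against a continuous outcome
#'
#' Discards the middle of the outcome distribution and asks how well the
#' score separates the extremes: positives are samples with outcome at or
#' below its lower quantile (lower ln(IC50) = more sensitive), negatives at
#' or above the upper quantile. AUC > 0.5 means a higher score identifies
#' the sensitive extreme. The AUC is computed from ranks and equals
#' Mann-Whitney U / (n_pos * n_neg); all-tied scores give AUC 0.5 with a
#' warning.
#'
#' @param score named numeric score per sample.
#' @param outcome named continuous outcome (e.g. ln(IC50)); lower = more
#'   sensitive.
#' @param qLo,qHi outcome quantiles bounding the extremes (defaults
#'   0.2 / 0.8).
#' @return a [ROCResult-class].
#' @examples
#' sc <- c(a = 0.9, b = 0.8, c = 0.2, d = 0.1)
#' out <- c(a = -2, b = -1.5, c = 1.5, d = 2)
#' extremeGroupROC(sc, out, qLo = 0.5, qHi = 0.5)
#' @export
extremeGroupROC <- function(score, outcome, qLo = 0.2, qHi = 0.8) {
  shared <- intersect(names(score), names(outcome))
  if (is.null(names(score)) || is.null(names(outcome))) {
    if (length(score) != length(outcome))
      stop("unnamed score and outcome must align")
    shared <- seq_along(score)
  }
  s <- score[shared]
  o <- outcome[shared]
  ok <- !is.na(s) & !is.na(o)
  s <- s[ok]; o <- o[ok]
  pos <- o <= quantileCut(o, qLo)
  neg <- o >= quantileCut(o, qHi)
  keep <- pos | neg
  if (!any(pos) || !any(neg))
    stop("an extreme subset is empty after available-case filtering")
  s <- s[keep]
  positive <- pos[keep]
  if (length(unique(s)) == 1L) {
    warning("all scores tied; AUC set to 0.5")
    return(new("ROCResult", auc = 0.5, nPos = sum(positive),
               nNeg = sum(!positive),
               operatingPoints = data.frame(threshold = s[1], tpr = 1,
                                            fpr = 1)))
  }
  new("ROCResult", auc = rankAUC(s, positive),
      nPos = as.integer(sum(positive)), nNeg = as.integer(sum(!positive)),
      operatingPoints = rocPoints(s, positive))
}

#' Binned outcome trend across score strata
#'
#' Equal-frequency bins on the score; per bin the sample count and median
#' outcome, plus a monotonicity statistic (Spearman correlation between bin
#' index and bin median).
#'
#' @param score,outcome named numeric vectors.
#' @param nBins number of bins (default 5).
#' @return list: `bins` (data.frame bin, n, medianOutcome), `monotonicity`.
#' @examples
#' s <- setNames(1:25, paste0("x", 1:25))
#' binnedTrend(s, -s, nBins = 5)$monotonicity  # -1
#' @export
binnedTrend <- function(score, outcome, nBins = 5L) {
  shared <- if (is.null(names(score))) seq_along(score)
            else intersect(names(score), names(outcome))
  s <- score[shared]; o <- outcome[shared]
  ok <- !is.na(s) & !is.na(o)
  s <- s[ok]; o <- o[ok]
  n <- length(s)
  if (n < nBins) stop("need at least nBins samples")
  bin <- ceiling(rank(s, ties.method = "first") * nBins / n)
  bins <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    data.frame(bin = b, n = sum(bin == b),
               medianOutcome = stats::median(o[bin == b]))
  }))
  list(bins = bins,
       monotonicity = spearman(bins$bin, bins$medianOutcome))
}

#' Proxy labels from marker-gene extremes
#'
#' When true drug response is unavailable in a cohort, a surrogate label is
#' built from the documented marker orientation: the proxy score is
#' z(positive marker) - z(negative marker) per sample (e.g. z(KLB) -
#' z(FGFR1)); samples at or above its upper quantile are "positive-like"
#' (sensitive-like), at or below the lower quantile "negative-like", the
#' middle excluded.
#'
#' @param expr cohort genes x samples matrix.
#' @param genePos,geneNeg marker gene ids (positively / negatively associated
#'   with sensitivity).
#' @param qLo,qHi quantile cutoffs (defaults 0.25 / 0.75, inclusive).
#' @return a [ProxyLabelSet-class].
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 40, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' makeProxyLabels(coh$expression, "KLB", "FGFR1")
#' @export
makeProxyLabels <- function(expr, genePos, geneNeg, qLo = 0.25, qHi = 0.75) {
  expr <- exprMatrix(expr)
  for (g in c(genePos, geneNeg))
    if (!g %in% rownames(expr)) stop("marker gene absent: ", g)
  z <- zscoreGenes(expr[c(genePos, geneNeg), , drop = FALSE])
  proxy <- z[genePos, ] - z[geneNeg, ]
  lab <- rep("excluded", ncol(expr))
  lab[proxy >= quantileCut(proxy, qHi)] <- "positive-like"
  lab[proxy <= quantileCut(proxy, qLo)] <- "negative-like"
  new("ProxyLabelSet",
      label = factor(stats::setNames(lab, colnames(expr)),
                     levels = c("positive-like", "negative-like",
                                "excluded")),
      proxyScore = stats::setNames(proxy, colnames(expr)),
      qLo = qLo, qHi = qHi)
}

#' Leakage-controlled proxy-label classification from signature genes
#'
#' Group-aware K-fold cross-validation on the labeled samples only: within
#' each fold, features are scaled with training parameters and a regularized
#' (ridge-penalized logistic) linear classifier is fitted on the training
#' split, with the penalty tuned by inner group-aware CV maximizing AUC;
#' pooled out-of-fold scores give the reported AUC. Folds whose training
#' split would contain a single class are merged with the next fold (logged
#' via a message). In external-cohort mode (`externalModel` supplied) CV is
#' skipped and the frozen model scores the cohort directly.
#'
#' @param expr cohort genes x samples matrix restricted to (or containing)
#'   the signature genes to use.
#' @param labels a [ProxyLabelSet-class] over the cohort samples (>= 3 per
#'   class).
#' @param genes optional gene subset to use (default: all rows of `expr`).
#' @param K outer folds (default 5, reduced automatically if classes are
#'   small).
#' @param seed integer seed.
#' @param lambda ridge penalty candidates (default 10^seq(-2, 1, length 4));
#'   inner AUC ties resolve toward the smallest penalty, since AUC is
#'   rank-based and pooled out-of-fold linear predictors from over-penalized
#'   fits degenerate toward fold-specific intercepts.
#' @param externalModel optional frozen model (as returned in `$model`) for
#'   transfer scoring.
#' @return list: `roc` (a [ROCResult-class]), `oofScore` (named), `model`
#'   (full-data frozen model for transfer), `folds`.
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 60, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' labs <- makeProxyLabels(coh$expression, "KLB", "FGFR1")
#' res <- oofProxyClassification(coh$expression, labs,
#'                               genes = grep("SIG", rownames(coh$expression),
#'                                            value = TRUE),
#'                               K = 3, seed = 1)
#' res$roc
#' @export
oofProxyClassification <- function(expr, labels, genes = NULL, K = 5L,
                                   seed = 1L,
                                   lambda = 10^seq(-2, 1, length.out = 4),
                                   externalModel = NULL) {
  expr <- exprMatrix(expr)
  stopifnot(is(labels, "ProxyLabelSet"))
  if (is.null(genes)) genes <- rownames(expr)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) stop("no usable genes")
  lab <- labels@label
  labeled <- names(lab)[lab != "excluded"]
  labeled <- intersect(labeled, colnames(expr))
  yBin <- as.integer(lab[labeled] == "positive-like")
  names(yBin) <- labeled
  if (!is.null(externalModel)) {
    sc <- externalModel$scaler
    Xs <- applyScale(t(expr[genes, labeled, drop = FALSE]), sc)
    eta <- as.numeric(stats::predict(externalModel$fit, newx = Xs,
                                     s = externalModel$lambda))
    names(eta) <- labeled
    roc <- new("ROCResult", auc = rankAUC(eta, yBin == 1L),
               nPos = as.integer(sum(yBin)),
               nNeg = as.integer(sum(yBin == 0L)),
               operatingPoints = rocPoints(eta, yBin == 1L))
    return(list(roc = roc, oofScore = eta, model = externalModel,
                folds = NULL))
  }
  if (sum(yBin) < 3L || sum(yBin == 0L) < 3L)
    stop("need at least 3 labeled samples per class")
  lambdaPath <- sort(lambda, decreasing = TRUE)
  fitRidgeLogit <- function(X, y) {
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambdaPath, standardize = FALSE)
  }
  plan <- makeFoldPlan(labeled, K = K, seed = seed)
  fold <- plan@fold
  # merge folds whose training split would be single-class
  repeat {
    bad <- which(vapply(seq_len(max(fold)), function(k) {
      tr <- yBin[fold != k]
      length(unique(tr)) < 2L
    }, logical(1)))
    if (!length(bad) || max(fold) <= 2L) break
    k <- bad[1]
    message("merging fold ", k, " (single-class training split)")
    fold[fold == max(fold)] <- k
    fold <- match(fold, sort(unique(fold)))
  }
  X <- t(expr[genes, labeled, drop = FALSE])
  eta <- stats::setNames(rep(NA_real_, length(labeled)), labeled)
  for (k in sort(unique(fold))) {
    tr <- fold != k
    sc <- scaleTrain(X[tr, , drop = FALSE])
    Xtr <- applyScale(X[tr, , drop = FALSE], sc)
    Xte <- applyScale(X[!tr, , drop = FALSE], sc)
    # inner penalty selection by group-aware CV maximizing AUC
    lamBest <- lambdaPath[1]
    if (length(lambdaPath) > 1L) {
      innerPlan <- makeFoldPlan(labeled[tr], K = min(3L, sum(tr) - 1L),
                                seed = stageSeed(seed, paste0("pin", k)))
      aucs <- matrix(NA_real_, length(lambdaPath), innerPlan@K)
      for (j in seq_len(innerPlan@K)) {
        itr <- innerPlan@fold != j
        if (length(unique(yBin[tr][itr])) < 2L ||
            length(unique(yBin[tr][!itr])) < 2L) next
        isc <- scaleTrain(Xtr[itr, , drop = FALSE])
        fit <- fitRidgeLogit(applyScale(Xtr[itr, , drop = FALSE], isc),
                             yBin[tr][itr])
        pv <- stats::predict(fit,
                             newx = applyScale(Xtr[!itr, , drop = FALSE],
                                               isc),
                             s = lambdaPath)
        for (li in seq_along(lambdaPath))
          aucs[li, j] <- rankAUC(pv[, li], yBin[tr][!itr] == 1L)
      }
      m <- rowMeans(aucs, na.rm = TRUE)
      m[is.nan(m)] <- -Inf
      asc <- order(lambdaPath)  # smallest penalty first on ties
      lamBest <- lambdaPath[asc][which.max(m[asc])]
    }
    fit <- fitRidgeLogit(Xtr, yBin[tr])
    eta[!tr] <- as.numeric(stats::predict(fit, newx = Xte, s = lamBest))
  }
  roc <- new("ROCResult", auc = rankAUC(eta, yBin == 1L),
             nPos = as.integer(sum(yBin)),
             nNeg = as.integer(sum(yBin == 0L)),
             operatingPoints = rocPoints(eta, yBin == 1L))
  scAll <- scaleTrain(X)
  fitAll <- fitRidgeLogit(applyScale(X, scAll), yBin)
  list(roc = roc, oofScore = eta,
       model = list(fit = fitAll, scaler = scAll,
                    lambda = stats::median(lambdaPath), genes = genes),
       folds = fold)
}

#' Cross-platform concordance of composite scores with ln(IC50)
#'
#' Per compound, Spearman correlation (asymptotic two-sided p) between the
#' panel-derived composite score and the second platform's ln(IC50) over
#' matched cell lines; negative rho is the expected orientation (higher
#' composite = more sensitive = lower ln(IC50)).
#'
#' @param scores a [CompositeScoreTable-class].
#' @param platformB data.frame with columns cellLine, compound, lnIC50.
#' @return data.frame: compound, rho, p, n.
#' @examples
#' cfg <- simulationConfig(nCellLines = 60, nDrugs = 8, nGenes = 20,
#'                         nSignatureGenes = 4, nMatchedLines = 40, seed = 4)
#' sim <- simulateCellLinePanel(cfg)
#' z <- standardizeAndOrient(sim$responses)
#' sc <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 10)))
#' gdsc <- simulateMatchedPlatform(sim$truth, cfg)
#' crossPlatformConcordance(sc, gdsc)
#' @export
crossPlatformConcordance <- function(scores, platformB) {
  stopifnot(is(scores, "CompositeScoreTable"))
  need <- c("cellLine", "compound", "lnIC50")
  if (!all(need %in% names(platformB)))
    stop("platformB needs columns ", paste(need, collapse = ", "))
  s <- scores@weightedScore
  out <- do.call(rbind, lapply(split(platformB, platformB$compound),
                               function(df) {
    matched <- intersect(df$cellLine, names(s))
    if (length(matched) < 3L) stop("fewer than 3 matched lines for ",
                                   df$compound[1])
    ic <- stats::setNames(df$lnIC50, df$cellLine)[matched]
    st <- spearmanTest(s[matched], ic)
    data.frame(compound = df$compound[1], rho = st$rho, p = st$p, n = st$n)
  }))
  rownames(out) <- NULL
  out
}

#' Multivariable linear model of sensitivity on signature and axis genes
#'
#' Ordinary least squares of the outcome on z-standardized covariates;
#' reports per covariate the standardized coefficient, standard error, 95\%
#' confidence interval and the rank of its absolute coefficient. Collinear
#' covariate sets (condition number above `kappaMax`) trigger a warning with
#' a variance-inflation report.
#'
#' @param outcome named numeric outcome (e.g. ln(IC50)).
#' @param covariates data.frame or matrix of covariates (rows = samples,
#'   named), e.g. signature score plus axis-gene expressions.
#' @param kappaMax condition-number warning threshold (default 30).
#' @return data.frame: covariate, estimate, se, ciLo, ciHi, p, rankAbs.
#' @examples
#' set.seed(1)
#' sig <- rnorm(50); g1 <- rnorm(50)
#' y <- -2 * scale(sig)[, 1] + rnorm(50, sd = 1e-9)
#' names(y) <- paste0("s", 1:50)
#' cov <- data.frame(signature = sig, FGFR1 = g1,
#'                   row.names = names(y))
#' multivariableModel(y, cov)
#' @export
multivariableModel <- function(outcome, covariates, kappaMax = 30) {
  covariates <- as.data.frame(covariates)
  shared <- intersect(names(outcome), rownames(covariates))
  if (length(shared)) {
    outcome <- outcome[shared]
    covariates <- covariates[shared, , drop = FALSE]
  }
  n <- length(outcome)
  if (n <= ncol(covariates) + 1L)
    stop("need n > number of covariates + 1")
  Z <- scale(as.matrix(covariates))
  cc <- suppressWarnings(stats::cor(Z))
  kap <- tryCatch(kappa(cc, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > kappaMax) {
    vif <- tryCatch(diag(solve(cc)), error = function(e)
      rep(Inf, ncol(Z)))
    warning("collinear covariates (condition number ",
            format(kap, digits = 3), "); VIF: ",
            paste(sprintf("%s=%.1f", colnames(Z), vif), collapse = ", "))
  }
  df <- data.frame(y = as.numeric(outcome), Z)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  ci <- stats::confint(fit)[-1, , drop = FALSE]
  out <- data.frame(covariate = colnames(Z),
                    estimate = sm[, 1], se = sm[, 2],
                    ciLo = ci[, 1], ciHi = ci[, 2], p = sm[, 4])
  out$rankAbs <- rank(-abs(out$estimate), ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Variance shares of the leading principal components of signature genes
#'
#' Gene-standardized PCA of the signature-gene submatrix; returns the
#' fractions of variance explained by the leading components (they sum to 1
#' over all components).
#'
#' @param expr genes x samples matrix restricted to the signature genes
#'   (>= 2 genes, >= 3 samples).
#' @param nComponents number of leading fractions to return (default 5).
#' @return numeric vector of variance fractions.
#' @examples
#' cfg <- simulationConfig(nCellLines = 30, nDrugs = 6, nGenes = 40,
#'                         nSignatureGenes = 6, cohortNSamples = 30, seed = 8)
#' coh <- simulateTumorCohort(cfg)
#' pcaAxisShare(coh$expression[paste0("SIG00", 1:6), ])
#' @export
pcaAxisShare <- function(expr, nComponents = 5L) {
  expr <- exprMatrix(expr)
  if (nrow(expr) < 2L || ncol(expr) < 3L)
    stop("need at least 2 genes and 3 samples")
  Z <- t(scale(t(expr)))
  keep <- apply(Z, 1L, function(x) all(is.finite(x)))
  pc <- stats::prcomp(t(Z[keep, , drop = FALSE]), center = FALSE,
                      scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  utils::head(frac, nComponents)
}
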