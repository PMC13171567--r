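scoreOf <- function(x, samples = names(x)) {
  new("SignatureScoreTable", sample = samples, score = unname(x),
      method = "updown", nGenesUsed = rep(1L, length(x)), params = list())
}

test_that("axis correlations report planted signs and degenerate statuses", {
  coh <- simulateTumorCohort(smallConfig(seed = 51L, cohortNSamples = 44L))
  sc <- scoreOf(coh$truth@cohortLatent)
  ax <- axisCorrelations(sc, coh$expression,
                         c("FGFR1", "KLB", "FGF19", "NOTAGENE"))
  expect_identical(ax$status, c("ok", "ok", "ok", "absent"))
  expect_lt(ax$rho[ax$gene == "FGFR1"], 0)
  expect_gt(ax$rho[ax$gene == "KLB"], 0)
  # a gene equal to the score correlates perfectly
  expr2 <- rbind(coh$expression,
                 SELF = coh$truth@cohortLatent)
  expect_equal(axisCorrelations(sc, expr2, "SELF")$rho, 1)

  # planted signs are significant in most replicates at study-like noise
  hits <- vapply(1:10, function(s) {
    coh <- simulateTumorCohort(smallConfig(seed = s, cohortNSamples = 44L))
    ax <- axisCorrelations(scoreOf(coh$truth@cohortLatent),
                           coh$expression, "FGFR1")
    ax$rho < 0 && ax$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("group comparison uses exact Mann-Whitney behavior", {
  # complete separation, 4 vs 4: exact two-sided p = 2/70
  expr <- matrix(c(sort(rnorm(8))), 1, 8,
                 dimnames = list("marker", paste0("s", 1:8)))
  sc <- scoreOf(setNames(c(1, 2, 3, 4, 10, 11, 12, 13), paste0("s", 1:8)))
  # with 8 samples the interpolated median lies between the middle values,
  # so inclusive cutoffs at 0.5/0.5 give a clean 4 vs 4 split
  res <- groupCompare(sc, expr, "marker", qHi = 0.5, qLo = 0.5)
  expect_equal(res$nHigh, 4L)
  expect_equal(res$nLow, 4L)
  expect_equal(res$p, 2 / 70, tolerance = 1e-12)
  # swapped groups: same p
  scSwap <- scoreOf(setNames(rev(c(1, 2, 3, 4, 10, 11, 12, 13)),
                             paste0("s", 1:8)))
  expect_equal(groupCompare(scSwap, expr, "marker",
                            qHi = 0.5, qLo = 0.5)$p, res$p)
  # identical distributions: p near 1
  scNull <- scoreOf(setNames(rep(c(1, 2, 3, 4), 2), paste0("s", 1:8)))
  expect_gt(groupCompare(scNull, expr, "marker",
                         qHi = 0.5, qLo = 0.5)$p, 0.5)
  expect_error(groupCompare(sc, expr, "absent"), "absent")
})

test_that("genome-wide association applies BH over all tested genes", {
  coh <- simulateTumorCohort(smallConfig(seed = 52L, cohortNSamples = 40L))
  sc <- scoreOf(coh$truth@cohortLatent)
  res <- genewideAssociation(sc, coh$expression)
  expect_setequal(res$gene, rownames(coh$expression))
  expect_equal(res$q, p.adjust(res$p, "BH")[order(order(res$p))][
    order(order(res$p))], tolerance = 1e-12, ignore_attr = TRUE)
  # planted up genes are among the strongest positive correlations
  top <- head(res$gene[order(-res$rho)], 15)
  beta <- coh$truth@signatureEffects
  posPlanted <- names(beta)[beta > 0]
  expect_gt(length(intersect(top, posPlanted)), 0)
  # null-only genes yield ~no BH discoveries
  nullExpr <- matrix(rnorm(1000 * 40), 1000, 40,
                     dimnames = list(sprintf("n%04d", 1:1000),
                                     coh$truth@cohortLatent |> names()))
  colnames(nullExpr) <- colnames(coh$expression)
  resNull <- genewideAssociation(sc, nullExpr)
  expect_lte(sum(resNull$significant), 2)
})

test_that("extreme-group ROC matches pairwise concordance and U identity", {
  sc <- c(a = 0.9, b = 0.8, c = 0.2, d = 0.1)
  out <- c(a = -2, b = -1.5, c = 1.5, d = 2)
  expect_equal(extremeGroupROC(sc, out, 0.5, 0.5)@auc, 1)
  # 3 of 4 positive/negative score pairs concordant
  sc2 <- c(a = 0.9, b = 0.2, c = 0.8, d = 0.1)
  out2 <- c(a = -2, b = -1.5, c = 2, d = 1.5)
  expect_equal(extremeGroupROC(sc2, out2, 0.5, 0.5)@auc, 3 / 4)
  # Mann-Whitney identity on random tables, exact
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    score <- rnorm(n)
    if (rep %% 3 == 0) score <- sample(round(score, 1))  # force ties
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(positive)) positive[1] <- TRUE
    if (all(positive)) positive[1] <- FALSE
    auc <- FGFRiScore:::rankAUC(score, positive)
    U <- wilcoxU(score, positive)
    expect_equal(auc, U / (sum(positive) * sum(!positive)),
                 tolerance = 1e-12)
  }
  # monotone transform invariance
  names(sc2) <- names(out2) <- c("a", "b", "c", "d")
  expect_equal(extremeGroupROC(exp(sc2), out2, 0.5, 0.5)@auc,
               extremeGroupROC(sc2, out2, 0.5, 0.5)@auc)
  # all-tied scores: AUC 0.5 with warning
  tied <- setNames(rep(1, 4), letters[1:4])
  expect_warning(r <- extremeGroupROC(tied, out, 0.5, 0.5), "tied")
  expect_equal(r@auc, 0.5)
})

test_that("binned trend is monotone for deterministic outcomes", {
  s <- setNames(rnorm(25), paste0("x", 1:25))
  bt <- binnedTrend(s, -s, nBins = 5)
  expect_equal(bt$monotonicity, -1)
  expect_equal(bt$bins$n, rep(5L, 5))
  expect_true(all(diff(bt$bins$medianOutcome) < 0))
  # independent outcome: small |monotonicity| on average
  set.seed(4)
  mono <- replicate(20, binnedTrend(setNames(rnorm(60), 1:60),
                                    setNames(rnorm(60), 1:60),
                                    nBins = 5)$monotonicity)
  expect_lt(abs(mean(mono)), 0.4)
})

test_that("proxy labels derive from the marker z-difference extremes", {
  coh <- simulateTumorCohort(smallConfig(seed = 53L, cohortNSamples = 40L))
  labs <- makeProxyLabels(coh$expression, "KLB", "FGFR1")
  tab <- table(labs@label)
  expect_gte(tab[["positive-like"]], 10)
  expect_gte(tab[["negative-like"]], 10)
  # counts stay near the quantile arithmetic (ties included)
  expect_lte(tab[["positive-like"]], 12)
  # gene_pos = -gene_neg gives proxy = 2 z(gene_pos)
  expr <- rbind(gp = rnorm(20), gn = 0)
  expr["gn", ] <- -expr["gp", ]
  colnames(expr) <- paste0("s", 1:20)
  labs2 <- makeProxyLabels(expr, "gp", "gn")
  zp <- (expr["gp", ] - mean(expr["gp", ])) / sd(expr["gp", ])
  expect_equal(labs2@proxyScore, 2 * zp)
  # labels agree with latent extremes most of the time
  agree <- vapply(1:5, function(s) {
    coh <- simulateTumorCohort(smallConfig(seed = s, cohortNSamples = 60L))
    labs <- makeProxyLabels(coh$expression, "KLB", "FGFR1")
    u <- coh$truth@cohortLatent
    lab <- labs@label[lab <- labs@label != "excluded"]
    truthLab <- ifelse(u[names(lab)] > median(u), "positive-like",
                       "negative-like")
    mean(as.character(lab) == truthLab)
  }, numeric(1))
  expect_gt(mean(agree), 0.7)
  expect_error(makeProxyLabels(coh$expression, "KLB", "NOPE"), "absent")
})

test_that("proxy OOF classification separates real labels, not permuted ones", {
  coh <- simulateTumorCohort(smallConfig(seed = 54L, cohortNSamples = 80L,
                                         nSignatureGenes = 10L))
  labs <- makeProxyLabels(coh$expression, "KLB", "FGFR1")
  sigGenes <- grep("^SIG", rownames(coh$expression), value = TRUE)
  res <- suppressWarnings(oofProxyClassification(
    coh$expression, labs, genes = sigGenes, K = 4, seed = 1))
  expect_gt(res$roc@auc, 0.7)
  # determinism
  res2 <- suppressWarnings(oofProxyClassification(
    coh$expression, labs, genes = sigGenes, K = 4, seed = 1))
  expect_identical(res$roc@auc, res2$roc@auc)
  # near-separable single-gene labels
  expr <- matrix(rnorm(3 * 60), 3, 60,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:60)))
  expr["gA", ] <- c(rnorm(30, -3, 0.2), rnorm(30, 3, 0.2))
  labsSep <- makeProxyLabels(expr, "gA", "gB", qLo = 0.4, qHi = 0.6)
  resSep <- suppressWarnings(oofProxyClassification(expr, labsSep, K = 3,
                                                    seed = 2))
  expect_gt(resSep$roc@auc, 0.95)
  # permuted labels: AUC hovers around chance
  aucNull <- vapply(1:10, function(s) {
    labP <- labs
    shuf <- withr::with_seed(s, sample(seq_along(labP@label)))
    labP@label <- setNames(labP@label[shuf], names(labP@label))
    suppressWarnings(oofProxyClassification(coh$expression, labP,
                                            genes = sigGenes,
                                            K = 4, seed = s)$roc@auc)
  }, numeric(1))
  expect_gt(mean(aucNull), 0.35)
  expect_lt(mean(aucNull), 0.65)
})

test_that("labels from genes disjoint from the signature carry no signal", {
  # averaged over independent cohorts, since a single cohort's background
  # genes can correlate with the latent axis by chance
  aucs <- vapply(1:6, function(s) {
    coh <- simulateTumorCohort(smallConfig(seed = 60L + s,
                                           cohortNSamples = 80L))
    expr <- coh$expression
    bg <- grep("^G", rownames(expr), value = TRUE)[1:2]
    labs <- makeProxyLabels(expr, bg[1], bg[2])
    sigGenes <- grep("^SIG", rownames(expr), value = TRUE)
    suppressWarnings(oofProxyClassification(expr, labs, genes = sigGenes,
                                            K = 4, seed = s)$roc@auc)
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("cross-platform concordance is negative under correct orientation", {
  cfg <- smallConfig(seed = 56L, nCellLines = 150L, nMatchedLines = 134L)
  sim <- simulateCellLinePanel(cfg)
  ph <- phenotypePipeline(sim)
  tab <- simulateMatchedPlatform(sim$truth, cfg)
  res <- crossPlatformConcordance(ph$scores, tab)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$rho < 0))
  expect_true(all(res$n == 134L))
  # noise-free: exactly -1
  cfg0 <- noiseFreeConfig(nMatchedLines = 30L)
  sim0 <- simulateCellLinePanel(cfg0)
  ph0 <- phenotypePipeline(sim0)
  res0 <- crossPlatformConcordance(ph0$scores,
                                   simulateMatchedPlatform(sim0$truth, cfg0))
  expect_equal(res0$rho, rep(-1, 2))
  # shuffled matching destroys the association
  tabShuf <- tab
  tabShuf$cellLine <- withr::with_seed(1, ave(tab$cellLine, tab$compound,
                                              FUN = sample))
  resShuf <- crossPlatformConcordance(ph$scores, tabShuf)
  expect_true(all(abs(resShuf$rho) < 0.25))
})

test_that("multivariable model recovers coefficients and flags collinearity", {
  set.seed(6)
  n <- 60
  sig <- rnorm(n)
  g1 <- rnorm(n); g2 <- rnorm(n)
  y <- setNames(-2 * scale(sig)[, 1], paste0("s", 1:n))
  cov <- data.frame(signature = sig, FGFR1 = g1, KLB = g2,
                    row.names = names(y))
  res <- multivariableModel(y, cov)
  expect_equal(res$estimate[res$covariate == "signature"], -2,
               tolerance = 1e-6)
  expect_equal(abs(res$estimate[res$covariate != "signature"]),
               c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(res$rankAbs[res$covariate == "signature"], 1L)
  # signature beats its own noisy single-gene proxies most of the time
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    u <- rnorm(80)
    sig <- u + rnorm(80, sd = 0.3)
    prox1 <- u + rnorm(80, sd = 1.2)
    prox2 <- -u + rnorm(80, sd = 1.2)
    y <- setNames(-1.5 * u + rnorm(80, sd = 0.5), paste0("s", 1:80))
    cov <- data.frame(signature = sig, g1 = prox1, g2 = prox2,
                      row.names = names(y))
    res <- multivariableModel(y, cov)
    res$rankAbs[res$covariate == "signature"] == 1L
  }, logical(1))
  expect_gte(sum(wins), 8)
  # identical covariates trigger the collinearity warning
  cov2 <- data.frame(a = sig, b = sig, row.names = names(y))
  expect_warning(multivariableModel(y, cov2), "collinear")
})

test_that("PCA axis shares behave at both extremes", {
  # rank-1 noise-free matrix: PC1 share 1
  u <- rnorm(30); v <- rnorm(10)
  m <- outer(v, u)
  dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:30))
  fr <- pcaAxisShare(m)
  expect_equal(fr[1], 1, tolerance = 1e-9)
  # isotropic noise, 20 genes: PC1 well below 0.5
  set.seed(7)
  m2 <- matrix(rnorm(20 * 100), 20, 100,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:100)))
  fr2 <- pcaAxisShare(m2, nComponents = 20)
  expect_lt(fr2[1], 0.5)
  expect_gt(fr2[1], 1 / 20)
  # shares sum to 1 over all components
  expect_equal(sum(pcaAxisShare(m2, nComponents = 100)), 1)
})
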