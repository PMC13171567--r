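toySignature <- function(up = "gUp", down = "gDown") {
  w <- setNames(c(rep(1, length(up)), rep(-1, length(down))), c(up, down))
  new("SignatureModel", meanWeight = w,
      foldWeights = cbind(w, w),
      stability = setNames(rep(1, length(w)), names(w)),
      upGenes = up, downGenes = down, nTop = length(w), stabilityMin = 0.8)
}

cohortFixture <- function(seed = 8L, ...) {
  simulateTumorCohort(smallConfig(seed = seed, ...))
}

test_that("signature derivation averages folds and scores sign stability", {
  # identical folds: stability 1, mean equals any fold
  cf <- cbind(f1 = c(gA = 1, gB = -2), f2 = c(gA = 1, gB = -2),
              f3 = c(gA = 1, gB = -2))
  sig <- deriveSignature(cf, nTop = 5, stabilityMin = 0.8)
  expect_equal(sig@stability, c(gA = 1, gB = 1))
  expect_equal(sig@meanWeight, cf[, 1])
  expect_identical(signatureGenes(sig), list(up = "gA", down = "gB"))

  # hand count: weights (+1, -1, +1, -1, +0.1) -> positive mean, 3/5 agree
  cf2 <- matrix(c(1, -1, 1, -1, 0.1), 1, 5,
                dimnames = list("gMix", paste0("f", 1:5)))
  cf2 <- rbind(cf2, gAnchor = rep(0.5, 5))
  sig2 <- deriveSignature(cf2, nTop = 5, stabilityMin = 0.5)
  expect_equal(sig2@stability[["gMix"]], 0.6)
  # below a 0.8 threshold the unstable gene is excluded
  sig3 <- deriveSignature(cf2, nTop = 5, stabilityMin = 0.8)
  expect_false("gMix" %in% sig3@upGenes)
  expect_error(deriveSignature(cf2[1, , drop = FALSE], stabilityMin = 0.9),
               "stability")
})

test_that("planted genes dominate a ridge signature at study-like SNR", {
  sim <- simulateCellLinePanel(smallConfig(seed = 41L, nCellLines = 120L,
                                           nGenes = 150L,
                                           nSignatureGenes = 15L))
  ph <- phenotypePipeline(sim)
  y <- ph$scores@weightedScore
  plan <- makeFoldPlan(names(y), K = 5, seed = 41)
  oof <- fitPredictOOF(sim$expression[, names(y)], y, plan,
                       modelSpec("ridge"), seed = 41)
  sig <- deriveSignature(foldCoefficients(oof), nTop = 15,
                         stabilityMin = 0.8)
  top15 <- names(sort(-abs(sig@meanWeight)))[1:15]
  expect_gte(mean(grepl("^SIG", top15)), 0.6)
})

test_that("up-down score follows its construction and available-case rule", {
  # two up genes at +1 SD, two down at -1 SD for sample s1, reversed for s2,
  # third sample at the cohort mean
  mk <- function(vals) matrix(vals, nrow = 1)
  expr <- rbind(
    u1 = c(1, -1, 0), u2 = c(1, -1, 0),
    d1 = c(-1, 1, 0), d2 = c(-1, 1, 0))
  # scale so each gene has cohort mean 0 sd 1: columns are already symmetric
  expr <- expr / apply(expr, 1, sd)
  colnames(expr) <- paste0("s", 1:3)
  sig <- toySignature(up = c("u1", "u2"), down = c("d1", "d2"))
  sc <- updownScore(expr, sig)
  expect_equal(sc@score[3], 0)               # sample at cohort mean
  expect_gt(sc@score[1], 0)
  expect_equal(sc@score[1], -sc@score[2])
  # masking a down gene equals recomputation on the reduced set
  exprMasked <- expr[c("u1", "u2", "d1"), ]
  scM <- updownScore(exprMasked, sig)
  sigRed <- toySignature(up = c("u1", "u2"), down = "d1")
  scRed <- updownScore(exprMasked, sigRed)
  expect_equal(scM@score, scRed@score)
  # negating the signature negates the score exactly
  swapped <- toySignature(up = c("d1", "d2"), down = c("u1", "u2"))
  expect_equal(updownScore(expr, swapped)@score, -sc@score)
  expect_error(updownScore(expr[c("d1", "d2"), ][0, , drop = FALSE], sig))
})

test_that("ssGSEA matches the hand recurrence and the brute-force oracle", {
  expr <- matrix(c(3, 2, 1), 3, 1,
                 dimnames = list(c("gA", "gB", "gC"), "s1"))
  # alpha 0: running sums (1, 1/2, 0) integrate to 1.5
  expect_equal(ssgseaScore(expr, upGenes = "gA", alpha = 0)@score, 1.5)
  # brute-force equivalence on random 50-gene samples
  set.seed(77)
  for (rep in 1:10) {
    G <- 50
    x <- setNames(rnorm(G), paste0("g", 1:G))
    inSet <- sample(names(x), 8)
    alpha <- sample(c(0, 0.25, 1), 1)
    em <- matrix(x, G, 1, dimnames = list(names(x), "s"))
    got <- ssgseaScore(em, upGenes = inSet, alpha = alpha)@score
    expect_lt(abs(got - bruteForceSSGSEA(x, inSet, alpha)), 1e-9)
  }
  # degenerate set equal to the universe
  expect_error(ssgseaScore(expr, upGenes = c("gA", "gB", "gC")),
               "universe")
  expect_error(ssgseaScore(expr, upGenes = "absent"), "intersect")
})

test_that("ssGSEA and rank scores are invariant to monotone transforms", {
  coh <- cohortFixture()
  expr <- coh$expression
  sig <- toySignature(up = c("SIG001", "SIG002"),
                      down = c("SIG003", "SIG004"))
  mono <- exp(expr / 2) + 1  # strictly monotone per-sample transform
  expect_equal(ssgseaScore(expr, sig@upGenes, sig@downGenes)@score,
               ssgseaScore(mono, sig@upGenes, sig@downGenes)@score)
  expect_equal(rankScore(expr, sig)@score, rankScore(mono, sig)@score)
  # and to gene/sample order
  perm <- expr[sample(nrow(expr)), sample(ncol(expr))]
  s1 <- rankScore(expr, sig)
  s2 <- rankScore(perm, sig)
  expect_equal(s1@score[match(s2@sample, s1@sample)], s2@score)
})

test_that("rank score follows its formula and bounds", {
  expr <- matrix(4:1, 4, 1,
                 dimnames = list(c("top", "mid1", "mid2", "bottom"), "s1"))
  sig <- toySignature(up = "top", down = "bottom")
  expect_equal(rankScore(expr, sig)@score, (4 - 1) / 4)  # 0.75
  # identical rank distributions cancel
  sig2 <- toySignature(up = c("top", "bottom"), down = c("mid1", "mid2"))
  expr2 <- matrix(c(4, 2, 3, 1), 4, 1,
                  dimnames = list(c("top", "mid1", "mid2", "bottom"), "s1"))
  expect_equal(rankScore(expr2, sig2)@score, 0)
  coh <- cohortFixture()
  sc <- rankScore(coh$expression,
                  toySignature(up = "SIG001", down = "SIG002"))
  expect_true(all(abs(sc@score) < 1))
})

test_that("elastic-net panel recovers exact support in the noiseless limit", {
  set.seed(5)
  n <- 60
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 paste0("s", 1:n)))
  coefs <- c(g01 = 2, g02 = -1.5, g03 = 1, g04 = -2.5, g05 = 3)
  y <- as.numeric(t(expr[names(coefs), ]) %*% coefs)
  names(y) <- colnames(expr)
  panel <- suppressWarnings(deriveReducedPanel(
    expr, y, size = 5, K = 3, seed = 1,
    spec = modelSpec("elastic_net",
                     grid = list(alpha = c(0.5, 0.9),
                                 lambda = 10^seq(-3, 0, length.out = 4)))))
  expect_setequal(panel@genes, names(coefs))
  # count contract at the default size
  sim <- simulateCellLinePanel(smallConfig(seed = 42L))
  ph <- phenotypePipeline(sim)
  y2 <- ph$scores@weightedScore
  p2 <- suppressWarnings(deriveReducedPanel(sim$expression[, names(y2)],
                                            y2, size = 8, K = 3, seed = 2))
  expect_lte(length(p2@genes), 8L)
})

test_that("panel score tracks the full signature on a fresh cohort", {
  sim <- simulateCellLinePanel(smallConfig(seed = 43L, nCellLines = 120L))
  ph <- phenotypePipeline(sim)
  y <- ph$scores@weightedScore
  plan <- makeFoldPlan(names(y), K = 5, seed = 43)
  oof <- fitPredictOOF(sim$expression[, names(y)], y, plan,
                       modelSpec("ridge"), seed = 43)
  sig <- deriveSignature(foldCoefficients(oof), nTop = 10,
                         stabilityMin = 0.8)
  panel <- suppressWarnings(deriveReducedPanel(
    sim$expression[, names(y)], y, size = 10, K = 3, seed = 43))
  coh <- simulateTumorCohort(smallConfig(seed = 43L, nCellLines = 120L),
                             sim$truth)
  full <- updownScore(coh$expression, sig)
  compact <- panelScore(coh$expression, panel)
  # frozen-seed calibrated floor (observed ~0.9 at this config)
  expect_gt(scoreConcordance(full, compact)$rho, 0.5)
})

test_that("score concordance matches hand ranks and rejects tiny overlap", {
  s1 <- new("SignatureScoreTable", sample = paste0("s", 1:5),
            score = c(1, 2, 3, 4, 5), method = "updown",
            nGenesUsed = rep(2L, 5), params = list())
  s2 <- new("SignatureScoreTable", sample = paste0("s", 1:5),
            score = c(1, 2, 3, 5, 4), method = "ssgsea",
            nGenesUsed = rep(2L, 5), params = list())
  expect_equal(scoreConcordance(s1, s2)$rho, 0.9)
  expect_equal(scoreConcordance(s1, s1)$rho, 1)
  s3 <- s1; s3@score <- -s1@score
  expect_equal(scoreConcordance(s1, s3)$rho, -1)
  s4 <- s1; s4@sample <- paste0("t", 1:5)
  expect_error(scoreConcordance(s1, s4), "shared")
})

test_that("all scoring methods recover the cohort latent axis", {
  hits <- sapply(1:5, function(s) {
    sim <- simulateCellLinePanel(smallConfig(seed = s, nCellLines = 120L))
    ph <- phenotypePipeline(sim)
    y <- ph$scores@weightedScore
    plan <- makeFoldPlan(names(y), K = 5, seed = s)
    oof <- fitPredictOOF(sim$expression[, names(y)], y, plan,
                         modelSpec("ridge", grid = list(lambda = c(1, 10,
                                                                   100))),
                         seed = s)
    sig <- deriveSignature(foldCoefficients(oof), nTop = 10,
                           stabilityMin = 0.8)
    coh <- simulateTumorCohort(smallConfig(seed = s, nCellLines = 120L),
                               sim$truth)
    u <- coh$truth@cohortLatent
    c(ud = cor(updownScore(coh$expression, sig)@score, u,
               method = "spearman"),
      ss = cor(ssgseaScore(coh$expression, sig@upGenes,
                           sig@downGenes)@score, u, method = "spearman"),
      rk = cor(rankScore(coh$expression, sig)@score, u,
               method = "spearman"))
  })
  expect_true(all(hits > 0))
})
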