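# Shared fixtures and independent oracles used across the suite.

smallConfig <- function(seed = 1L, ...) {
  args <- list(nCellLines = 80L, nDrugs = 10L, nGenes = 100L,
               nSignatureGenes = 10L, nLineages = 4L, nMatchedLines = 40L,
               cohortNSamples = 40L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}

noiseFreeConfig <- function(seed = 1L, ...) {
  smallConfig(seed = seed, drugNoiseSd = 0, missingRate = 0,
              geneNoiseSd = 1e-9, lineageShiftSd = 0, ic50NoiseSd = 0,
              discordantFraction = 0, ...)
}

makeResponse <- function(m) {
  new("DrugResponseMatrix", values = m, qcLog = character(0))
}

phenotypePipeline <- function(sim, minOverlap = 10L, minCoverage = 0.8) {
  z <- standardizeAndOrient(filterDrugsByCoverage(sim$responses,
                                                  minCoverage))
  qc <- computeWeights(pairwiseConcordance(z, minOverlap = minOverlap))
  list(z = z, qc = qc,
       scores = suppressWarnings(compositeScores(z, qc)))
}

# Independent brute-force ssGSEA oracle: literal recurrence, no shared code
# with the package implementation.
bruteForceSSGSEA <- function(x, inSet, alpha) {
  stopifnot(!is.null(names(x)))
  ordNames <- names(sort(x, decreasing = TRUE))
  G <- length(x)
  ascRank <- rank(x, ties.method = "average")
  inWeights <- numeric(0)
  for (g in ordNames) {
    inWeights <- c(inWeights, if (g %in% inSet) ascRank[g]^alpha else 0)
  }
  outFlag <- !(ordNames %in% inSet)
  es <- 0
  cumIn <- 0
  cumOut <- 0
  for (i in seq_len(G)) {
    cumIn <- cumIn + inWeights[i] / sum(inWeights)
    cumOut <- cumOut + outFlag[i] / sum(outFlag)
    es <- es + (cumIn - cumOut)
  }
  unname(es)
}

# Mann-Whitney U from wilcox.test, for the AUC identity checks.
wilcoxU <- function(score, positive) {
  unname(suppressWarnings(
    stats::wilcox.test(score[positive], score[!positive])$statistic))
}
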