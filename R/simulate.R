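#' Build a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 476-line pan-cancer panel screened against 24 FGFR-targeting compounds at a
#' single concentration (log2 fold-change viability, ~10\% missing), 2,000
#' background genes of which 30 are linearly coupled to the latent sensitivity
#' axis, 8 lineages, a 134-line subset re-assayed on a second platform as
#' ln(IC50), and a 44-sample tumor cohort carrying named receptor-axis analogs
#' (FGFR1/2/3 negatively coupled, KLB positively, FGF19 uncoupled).
#'
#' @param nCellLines,nDrugs,nGenes,nSignatureGenes panel dimensions.
#' @param drugLoadingRange interval the per-drug fidelity loadings a_d are
#'   drawn from (uniformly).
#' @param discordantFraction fraction of drugs given loading ~0 ("discordant
#'   compounds" that exercise the weight floor).
#' @param drugNoiseSd SD of the additive Gaussian noise on drug responses.
#' @param missingRate MCAR masking probability in [0, 1).
#' @param missingMode "mcar" (default) or "block" (whole drug columns masked
#'   for a random subset of lines).
#' @param geneEffectSd magnitude scale of the planted gene couplings beta_g.
#' @param geneNoiseSd SD of expression noise.
#' @param nLineages,lineageShiftSd lineage count and SD of per-lineage,
#'   per-gene expression shifts.
#' @param nMatchedLines lines re-assayed on the second platform.
#' @param ic50Slope,ic50NoiseSd slope (< 0) and noise SD of the ln(IC50)
#'   transform of the latent axis.
#' @param cohortNSamples tumor-cohort size.
#' @param axisGeneSigns named vector in \{-1, 0, +1\}: coupling sign of each
#'   named axis gene.
#' @param seed integer master seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nCellLines = 50, nDrugs = 8, nGenes = 100,
#'                         nSignatureGenes = 10, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nCellLines = 476L, nDrugs = 24L,
                             nGenes = 2000L, nSignatureGenes = 30L,
                             drugLoadingRange = c(0.3, 0.9),
                             discordantFraction = 0.1,
                             drugNoiseSd = 1.5, missingRate = 0.1,
                             missingMode = "mcar",
                             geneEffectSd = 0.7, geneNoiseSd = 1,
                             nLineages = 8L, lineageShiftSd = 0.5,
                             nMatchedLines = 134L,
                             ic50Slope = -1.2, ic50NoiseSd = 0.8,
                             cohortNSamples = 44L,
                             axisGeneSigns = c(FGFR1 = -1, FGFR2 = -1,
                                               FGFR3 = -1, KLB = 1,
                                               FGF19 = 0),
                             seed = 1L) {
  nMatchedLines <- min(as.integer(nMatchedLines), as.integer(nCellLines))
  new("SimulationConfig",
      nCellLines = as.integer(nCellLines), nDrugs = as.integer(nDrugs),
      nGenes = as.integer(nGenes),
      nSignatureGenes = as.integer(nSignatureGenes),
      drugLoadingRange = as.numeric(drugLoadingRange),
      discordantFraction = discordantFraction,
      drugNoiseSd = drugNoiseSd, missingRate = missingRate,
      missingMode = missingMode,
      geneEffectSd = geneEffectSd, geneNoiseSd = geneNoiseSd,
      nLineages = as.integer(nLineages), lineageShiftSd = lineageShiftSd,
      nMatchedLines = nMatchedLines,
      ic50Slope = ic50Slope, ic50NoiseSd = ic50NoiseSd,
      cohortNSamples = as.integer(cohortNSamples),
      axisGeneSigns = axisGeneSigns, seed = as.integer(seed))
}

geneNames <- function(config) {
  sig <- sprintf("SIG%03d", seq_len(config@nSignatureGenes))
  bg <- sprintf("G%04d", seq_len(config@nGenes - config@nSignatureGenes))
  all <- c(sig, bg)
  if (length(intersect(names(config@axisGeneSigns), all)))
    stop("axis gene names collide with simulated gene names")
  list(signature = sig, background = bg, all = all)
}

#' Simulate a cell-line drug-response panel with matched expression
#'
#' Generates the latent-axis model the downstream analysis assumes: each cell
#' line i carries a latent sensitivity s_i ~ N(0, 1); drug d responds as
#' r_{i,d} = -a_d s_i + b_d + eps with fidelity loading a_d, a per-drug offset
#' b_d (so raw columns differ in location/scale and standardization is
#' non-trivial) and Gaussian noise, so higher latent sensitivity gives more
#' negative viability log2 fold-change. Entries are masked missing completely
#' at random (or block-wise). Planted signature genes are linearly coupled to
#' s_i (x_{g,i} = beta_g s_i + lineage shift + noise); the remaining genes
#' are lineage-shifted noise. Named axis genes are appended with couplings
#' following their configured signs.
#'
#' @param config a [SimulationConfig-class].
#' @return A list: `responses` ([DrugResponseMatrix-class]), `expression`
#'   (genes x cell lines matrix, axis genes included), `lineages` (factor),
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 40, nDrugs = 6, nGenes = 50, nSignatureGenes = 5, seed = 3))
#' sim$responses
#' @export
simulateCellLinePanel <- function(config) {
  validObject(config)
  gn <- geneNames(config)
  withSeed(stageSeed(config@seed, "panel"), {
    n <- config@nCellLines
    lines <- sprintf("CL%04d", seq_len(n))
    s <- stats::rnorm(n)
    names(s) <- lines
    lineage <- factor(sprintf("lineage%02d",
                              sample.int(config@nLineages, n, replace = TRUE)))

    a <- stats::runif(config@nDrugs, config@drugLoadingRange[1],
                      config@drugLoadingRange[2])
    nDisc <- floor(config@discordantFraction * config@nDrugs)
    if (nDisc > 0) a[sample.int(config@nDrugs, nDisc)] <- 0
    names(a) <- sprintf("FGFRi_%02d", seq_len(config@nDrugs))
    b <- stats::rnorm(config@nDrugs, mean = 0, sd = 1.5)

    r <- -outer(s, a) + matrix(b, n, config@nDrugs, byrow = TRUE) +
      matrix(stats::rnorm(n * config@nDrugs, sd = config@drugNoiseSd),
             n, config@nDrugs)
    dimnames(r) <- list(lines, names(a))

    if (config@missingRate > 0) {
      if (config@missingMode == "mcar") {
        mask <- matrix(stats::runif(n * config@nDrugs) < config@missingRate,
                       n, config@nDrugs)
      } else {
        # block mode: each line loses a random subset of whole drug columns
        mask <- matrix(FALSE, n, config@nDrugs)
        nMaskedLines <- round(n * min(1, 2 * config@missingRate))
        maskedLines <- sample.int(n, nMaskedLines)
        for (i in maskedLines) {
          k <- max(1L, stats::rbinom(1L, config@nDrugs, 0.5))
          mask[i, sample.int(config@nDrugs, k)] <- TRUE
        }
      }
      r[mask] <- NA_real_
    }

    beta <- stats::setNames(numeric(config@nGenes), gn$all)
    sgn <- sample(c(-1, 1), config@nSignatureGenes, replace = TRUE)
    beta[gn$signature] <- sgn * stats::runif(config@nSignatureGenes, 0.5, 1.5) *
      config@geneEffectSd

    shift <- matrix(stats::rnorm(config@nGenes * config@nLineages,
                                 sd = config@lineageShiftSd),
                    config@nGenes, config@nLineages,
                    dimnames = list(gn$all, levels(lineage)))
    # axis genes: coupling sign from config, magnitude = geneEffectSd
    axisBeta <- config@axisGeneSigns * config@geneEffectSd
    axisShift <- matrix(stats::rnorm(length(axisBeta) * config@nLineages,
                                     sd = config@lineageShiftSd),
                        length(axisBeta), config@nLineages,
                        dimnames = list(names(axisBeta), levels(lineage)))
    allBeta <- c(beta, axisBeta)
    allShift <- rbind(shift, axisShift)
    ng <- length(allBeta)
    expr <- outer(allBeta, s) +
      allShift[, as.integer(factor(lineage, levels = levels(lineage)))] +
      matrix(stats::rnorm(ng * n, sd = config@geneNoiseSd), ng, n)
    dimnames(expr) <- list(names(allBeta), lines)

    truth <- new("GroundTruth", latentSensitivity = s, drugLoadings = a,
                 signatureEffects = beta, lineageLabels = lineage,
                 cohortLatent = numeric(0))
    list(responses = new("DrugResponseMatrix", values = r,
                         qcLog = character(0)),
         expression = expr, lineages = lineage, truth = truth)
  })
}

#' Simulate a matched second-platform sensitivity table
#'
#' Draws a random subset of matched cell lines and emits, per compound, a
#' noisy monotone-decreasing ln(IC50) transform of the latent sensitivity:
#' ln(IC50) = slope * s_i + intercept + noise with slope < 0, so higher
#' latent sensitivity means lower ln(IC50).
#'
#' @param truth the [GroundTruth-class] from [simulateCellLinePanel()].
#' @param config the same [SimulationConfig-class].
#' @param compounds character vector of compound names for the second
#'   platform (two representative inhibitors by default).
#' @return data.frame with columns `cellLine`, `compound`, `lnIC50`
#'   (one row per matched line per compound).
#' @examples
#' cfg <- simulationConfig(nCellLines = 40, nDrugs = 6, nGenes = 50,
#'                         nSignatureGenes = 5, nMatchedLines = 20, seed = 3)
#' sim <- simulateCellLinePanel(cfg)
#' head(simulateMatchedPlatform(sim$truth, cfg))
#' @export
simulateMatchedPlatform <- function(truth, config,
                                    compounds = c("AZD4547-like",
                                                  "PD173074-like")) {
  validObject(config)
  s <- truth@latentSensitivity
  if (config@nMatchedLines > length(s))
    stop("nMatchedLines exceeds the number of simulated cell lines")
  withSeed(stageSeed(config@seed, "matched"), {
    matched <- sort(sample(names(s), config@nMatchedLines))
    out <- do.call(rbind, lapply(compounds, function(cmp) {
      intercept <- stats::rnorm(1, mean = 2, sd = 0.5)
      data.frame(cellLine = matched, compound = cmp,
                 lnIC50 = config@ic50Slope * s[matched] + intercept +
                   stats::rnorm(length(matched), sd = config@ic50NoiseSd),
                 row.names = NULL)
    }))
    out
  })
}

#' Simulate a tumor cohort with planted axis-gene structure
#'
#' Tumor samples carry a cohort latent axis; planted signature genes couple
#' to it with the same effects beta_g as in the cell-line panel, and named
#' axis genes couple with their configured signs (sign 0 = uncoupled pure
#' noise), emulating a cohort where the projected signature should correlate
#' negatively with the receptor analogs and positively with the co-receptor.
#'
#' @param config a [SimulationConfig-class].
#' @param truth optional [GroundTruth-class]; when supplied, the planted gene
#'   effects are reused so the cohort matches the panel the signature was
#'   learned on. Otherwise effects are drawn afresh from the config.
#' @return list: `expression` (genes x samples matrix including axis genes),
#'   `truth` (a [GroundTruth-class] whose `cohortLatent` slot is filled).
#' @examples
#' cfg <- simulationConfig(nCellLines = 40, nDrugs = 6, nGenes = 50,
#'                         nSignatureGenes = 5, cohortNSamples = 20, seed = 3)
#' coh <- simulateTumorCohort(cfg)
#' dim(coh$expression)
#' @export
simulateTumorCohort <- function(config, truth = NULL) {
  validObject(config)
  gn <- geneNames(config)
  if (is.null(truth)) {
    truth <- withSeed(stageSeed(config@seed, "cohort-effects"), {
      beta <- stats::setNames(numeric(config@nGenes), gn$all)
      sgn <- sample(c(-1, 1), config@nSignatureGenes, replace = TRUE)
      beta[gn$signature] <- sgn *
        stats::runif(config@nSignatureGenes, 0.5, 1.5) * config@geneEffectSd
      new("GroundTruth", latentSensitivity = numeric(0),
          drugLoadings = numeric(0), signatureEffects = beta,
          lineageLabels = factor(character(0)), cohortLatent = numeric(0))
    })
  }
  beta <- truth@signatureEffects
  if (length(intersect(names(config@axisGeneSigns), names(beta))))
    stop("axis gene names collide with signature gene names")
  withSeed(stageSeed(config@seed, "cohort"), {
    m <- config@cohortNSamples
    samples <- sprintf("TUMOR%03d", seq_len(m))
    u <- stats::rnorm(m)
    names(u) <- samples
    axisBeta <- config@axisGeneSigns * config@geneEffectSd
    allBeta <- c(beta, axisBeta)
    ng <- length(allBeta)
    expr <- outer(allBeta, u) +
      matrix(stats::rnorm(ng * m, sd = config@geneNoiseSd), ng, m)
    dimnames(expr) <- list(names(allBeta), samples)
    truthOut <- new("GroundTruth", latentSensitivity = truth@latentSensitivity,
                    drugLoadings = truth@drugLoadings,
                    signatureEffects = beta,
                    lineageLabels = truth@lineageLabels, cohortLatent = u)
    list(expression = expr, truth = truthOut)
  })
}
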