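#' @import methods
NULL

#' Simulation configuration for the synthetic pharmacogenomic generator
#'
#' Holds every tunable of the synthetic-data module: the size of the cell-line
#' panel, the drug panel and its fidelity/noise structure, planted signature
#' genes, lineage structure, the matched second-platform subset, and the tumor
#' cohort. Construct with [simulationConfig()], which supplies defaults that
#' emulate the study conditions (476 lines, 24 FGFR-panel drugs, 2,000 genes,
#' 30 planted signature genes, 10\% missingness, 134 matched lines, a 44-sample
#' tumor cohort).
#'
#' @slot nCellLines,nDrugs,nGenes,nSignatureGenes panel dimensions.
#' @slot drugLoadingRange length-2 numeric; drug fidelity loadings a_d are
#'   drawn uniformly from this interval (all non-negative).
#' @slot discordantFraction fraction of drugs whose loading is set to ~0,
#'   exercising the non-negativity floor of the reliability weights.
#' @slot drugNoiseSd,geneEffectSd,geneNoiseSd,lineageShiftSd noise scales.
#' @slot missingRate MCAR masking probability in [0, 1).
#' @slot missingMode "mcar" or "block" (whole drug columns masked per line
#'   subset, mimicking panel-coverage structure).
#' @slot nLineages,nMatchedLines,cohortNSamples counts.
#' @slot ic50Slope negative real: slope of the noisy monotone ln(IC50)
#'   transform of the latent axis.
#' @slot ic50NoiseSd noise SD of the ln(IC50) transform.
#' @slot axisGeneSigns named numeric in {-1, 0, +1}: coupling sign of each
#'   named receptor/co-receptor analog to the latent axis.
#' @slot seed integer master seed; identical config + seed gives bit-identical
#'   outputs.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nCellLines = "integer", nDrugs = "integer", nGenes = "integer",
  nSignatureGenes = "integer",
  drugLoadingRange = "numeric", discordantFraction = "numeric",
  drugNoiseSd = "numeric", missingRate = "numeric", missingMode = "character",
  geneEffectSd = "numeric", geneNoiseSd = "numeric",
  nLineages = "integer", lineageShiftSd = "numeric",
  nMatchedLines = "integer", ic50Slope = "numeric", ic50NoiseSd = "numeric",
  cohortNSamples = "integer", axisGeneSigns = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nCellLines = object@nCellLines, nDrugs = object@nDrugs,
           nGenes = object@nGenes, nSignatureGenes = object@nSignatureGenes,
           nLineages = object@nLineages, cohortNSamples = object@cohortNSamples)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be positive")
  if (object@nSignatureGenes > object@nGenes)
    msg <- c(msg, "nSignatureGenes must not exceed nGenes")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (!object@missingMode %in% c("mcar", "block"))
    msg <- c(msg, "missingMode must be 'mcar' or 'block'")
  if (length(object@drugLoadingRange) != 2L ||
      any(object@drugLoadingRange < 0) || diff(object@drugLoadingRange) < 0)
    msg <- c(msg, "drugLoadingRange must be a non-decreasing pair of non-negative reals")
  if (object@discordantFraction < 0 || object@discordantFraction >= 1)
    msg <- c(msg, "discordantFraction must lie in [0, 1)")
  if (object@nMatchedLines > object@nCellLines)
    msg <- c(msg, "nMatchedLines must not exceed nCellLines")
  if (object@ic50Slope >= 0) msg <- c(msg, "ic50Slope must be negative")
  if (is.null(names(object@axisGeneSigns)) ||
      any(!object@axisGeneSigns %in% c(-1, 0, 1)))
    msg <- c(msg, "axisGeneSigns must be a named vector of -1, 0, +1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated panel or cohort
#'
#' Returned alongside simulated data so recovery of the latent sensitivity
#' axis, the drug loadings and the planted signature genes can be tested
#' directly.
#'
#' @slot latentSensitivity per-cell-line latent sensitivity s_i.
#' @slot drugLoadings per-drug fidelity a_d on the latent axis.
#' @slot signatureEffects per-gene coupling beta_g (zero off the planted set).
#' @slot lineageLabels per-cell-line lineage factor.
#' @slot cohortLatent per-tumor-sample latent axis (empty until a cohort is
#'   simulated).
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  latentSensitivity = "numeric", drugLoadings = "numeric",
  signatureEffects = "numeric", lineageLabels = "factor",
  cohortLatent = "numeric"
))

setValidity("GroundTruth", function(object) {
  if (length(object@latentSensitivity) &&
      length(object@lineageLabels) != length(object@latentSensitivity))
    return("lineageLabels must align with latentSensitivity")
  TRUE
})

#' Raw drug-response matrix (cell lines x drugs)
#'
#' Replicate-collapsed log2 fold-change viability values with missing entries
#' allowed. Rows are cell lines, columns drugs; more negative values mean
#' stronger growth inhibition.
#'
#' @slot values numeric matrix with dimnames; NA marks unmeasured pairs.
#' @slot qcLog character log of filtering events applied to this object.
#' @exportClass DrugResponseMatrix
setClass("DrugResponseMatrix",
         representation(values = "matrix", qcLog = "character"))

setValidity("DrugResponseMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry cell-line rownames and drug colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate cell-line ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate drug ids")
  }
  if (ncol(v) > 0 && any(colSums(!is.na(v)) < 2L))
    msg <- c(msg, "each drug needs at least 2 non-missing values")
  if (length(msg)) msg else TRUE
})

#' Standardized, sensitivity-oriented response matrix
#'
#' Per-drug z-scores flipped so that larger values mean higher sensitivity:
#' z_{i,d} = -(r_{i,d} - mu_d) / sigma_d, computed over non-missing entries.
#'
#' @slot values oriented z-score matrix (same axes as the raw matrix).
#' @slot mu,sigma per-drug mean and sample SD used in standardization.
#' @slot oriented logical flag recording that the x(-1) flip was applied.
#' @exportClass StandardizedResponseMatrix
setClass("StandardizedResponseMatrix", representation(
  values = "matrix", mu = "numeric", sigma = "numeric", oriented = "logical"
))

setValidity("StandardizedResponseMatrix", function(object) {
  v <- object@values
  ok <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j][!is.na(v[, j])]
    abs(mean(x)) < 1e-9 && abs(stats::sd(x) - 1) < 1e-9
  }, logical(1))
  if (!all(ok)) return("each drug column must have mean 0 and unit SD")
  TRUE
})

#' Per-drug panel quality control: coverage, concordance, reliability weights
#'
#' @slot coverage c_d = n_d / N per drug.
#' @slot meanConcordance rho-bar_d: mean available off-diagonal pairwise
#'   Spearman correlation with the rest of the panel (NA if no valid pair).
#' @slot weights reliability weight w_d = c_d * max(0, rho-bar_d).
#' @slot concordance symmetric pairwise Spearman matrix (unit diagonal; NA
#'   where overlap < minOverlap).
#' @slot overlap pairwise overlap counts.
#' @slot minOverlap the overlap threshold used.
#' @exportClass DrugPanelQC
setClass("DrugPanelQC", representation(
  coverage = "numeric", meanConcordance = "numeric", weights = "numeric",
  concordance = "matrix", overlap = "matrix", minOverlap = "integer"
))

setValidity("DrugPanelQC", function(object) {
  m <- object@concordance
  if (nrow(m) && (!isTRUE(all.equal(m, t(m))) ||
                  any(abs(diag(m) - 1) > 1e-12, na.rm = TRUE)))
    return("concordance matrix must be symmetric with unit diagonal")
  if (length(object@weights) && any(object@weights < 0, na.rm = TRUE))
    return("weights must be non-negative")
  TRUE
})

#' Composite sensitivity score table
#'
#' Per cell line: the unweighted composite S_i (mean oriented z over the
#' line's measured drug set D_i) and the reliability-weighted composite S_i^w
#' (weights renormalized within D_i), with QC counts.
#'
#' @slot score,weightedScore per-line composites (NA when no drug measured).
#' @slot nDrugs size of D_i per line.
#' @slot weightSum sum of raw (pre-renormalization) weights over D_i.
#' @slot fallback lines where all available weights were 0 and the weighted
#'   score fell back to the unweighted one.
#' @exportClass CompositeScoreTable
setClass("CompositeScoreTable", representation(
  score = "numeric", weightedScore = "numeric", nDrugs = "integer",
  weightSum = "numeric", fallback = "logical"
))

setValidity("CompositeScoreTable", function(object) {
  if (!all(is.na(object@score) == (object@nDrugs == 0L)))
    return("score must be missing exactly when no drug is measured")
  TRUE
})

#' Split-half reliability result
#'
#' @slot rho per-repeat Spearman correlation between composites computed from
#'   two disjoint random halves of the drug panel.
#' @slot assignments list of logical vectors (TRUE = half A) per repeat.
#' @slot seed integer seed used.
#' @slot skipped number of repeats skipped for insufficient overlap.
#' @exportClass SplitHalfResult
setClass("SplitHalfResult", representation(
  rho = "numeric", assignments = "list", seed = "integer", skipped = "integer"
))

#' Group-aware cross-validation fold plan
#'
#' @slot fold integer outer-fold index per sample; samples sharing a group id
#'   share a fold.
#' @slot groups character group id per sample.
#' @slot K number of folds.
#' @slot seed integer seed.
#' @exportClass FoldPlan
setClass("FoldPlan", representation(
  fold = "integer", groups = "character", K = "integer", seed = "integer"
))

setValidity("FoldPlan", function(object) {
  if (length(object@fold) != length(object@groups))
    return("fold and groups must align")
  if (any(tapply(object@fold, object@groups,
                 function(f) length(unique(f))) != 1L))
    return("samples sharing a group id must share a fold")
  TRUE
})

#' Model family and tuning grid specification
#'
#' @slot family one of "ridge", "elastic_net", "svr_rbf", "random_forest".
#' @slot grid named list of candidate hyperparameter values.
#' @slot innerK inner group-aware folds used for tuning (default 3).
#' @exportClass ModelSpec
setClass("ModelSpec", representation(
  family = "character", grid = "list", innerK = "integer"
))

setValidity("ModelSpec", function(object) {
  if (!object@family %in% c("ridge", "elastic_net", "svr_rbf", "random_forest"))
    return("unknown model family")
  if (any(lengths(object@grid) == 0L))
    return("each tunable hyperparameter needs a non-empty candidate set")
  TRUE
})

#' Out-of-fold prediction result
#'
#' Each sample is predicted exactly once, by the model fitted on the outer
#' training split that excludes the sample's fold; per-fold scaling
#' parameters, selected hyperparameters and (for linear families) fitted
#' coefficients are retained for leakage audits and signature derivation.
#'
#' @slot observed,predicted named per-sample vectors.
#' @slot fold outer-fold index per sample.
#' @slot foldModels list (one per fold) with elements `params`, `center`,
#'   `scale`, `genes`, and `coefficients` (linear families only).
#' @slot family model family used.
#' @slot seed integer seed.
#' @exportClass OOFResult
setClass("OOFResult", representation(
  observed = "numeric", predicted = "numeric", fold = "integer",
  foldModels = "list", family = "character", seed = "integer"
))

setValidity("OOFResult", function(object) {
  n <- length(object@observed)
  if (length(object@predicted) != n || length(object@fold) != n)
    return("observed, predicted and fold must align")
  if (anyNA(object@fold)) return("every sample needs a fold assignment")
  TRUE
})

#' Permutation-test result for out-of-fold performance
#'
#' @slot rhoObs observed OOF Spearman correlation.
#' @slot rhoNull B null correlations from label permutations.
#' @slot p one-sided empirical p = (1 + #\{rho_b >= rho_obs\}) / (B + 1).
#' @slot seed integer seed.
#' @exportClass PermutationResult
setClass("PermutationResult", representation(
  rhoObs = "numeric", rhoNull = "numeric", p = "numeric", seed = "integer"
))

setValidity("PermutationResult", function(object) {
  B <- length(object@rhoNull)
  pexp <- (1 + sum(object@rhoNull >= object@rhoObs)) / (B + 1)
  if (abs(object@p - pexp) > 1e-15)
    return("p must equal (1 + #{rho_b >= rho_obs}) / (B + 1) exactly")
  TRUE
})

#' Fold-averaged linear gene signature
#'
#' @slot meanWeight fold-averaged coefficient per gene (standardized-feature
#'   scale).
#' @slot foldWeights genes x folds coefficient matrix.
#' @slot stability per-gene fraction of folds whose coefficient sign matches
#'   the mean's sign.
#' @slot upGenes,downGenes selected positive- and negative-weight gene sets.
#' @slot nTop,stabilityMin selection parameters.
#' @exportClass SignatureModel
setClass("SignatureModel", representation(
  meanWeight = "numeric", foldWeights = "matrix", stability = "numeric",
  upGenes = "character", downGenes = "character",
  nTop = "integer", stabilityMin = "numeric"
))

setValidity("SignatureModel", function(object) {
  if (length(intersect(object@upGenes, object@downGenes)))
    return("up and down sets must be disjoint")
  if (any(object@meanWeight[object@upGenes] <= 0) ||
      any(object@meanWeight[object@downGenes] >= 0))
    return("up genes need positive mean weight, down genes negative")
  TRUE
})

#' Per-sample signature activity scores
#'
#' @slot sample sample ids.
#' @slot score per-sample activity under the named method.
#' @slot method one of "updown", "ssgsea", "rank", "panel".
#' @slot nGenesUsed per-sample count of signature genes available.
#' @slot params parameter record (alpha, normalization, panel size, ...).
#' @exportClass SignatureScoreTable
setClass("SignatureScoreTable", representation(
  sample = "character", score = "numeric", method = "character",
  nGenesUsed = "integer", params = "list"
))

setValidity("SignatureScoreTable", function(object) {
  if (length(object@score) != length(object@sample))
    return("one score per sample")
  if (!object@method %in% c("updown", "ssgsea", "rank", "panel"))
    return("unknown scoring method")
  if (object@method == "rank" &&
      any(abs(object@score) >= 1 + 1e-12, na.rm = TRUE))
    return("rank-method scores must lie in (-1, 1)")
  TRUE
})

#' Elastic-net reduced gene panel
#'
#' @slot genes ordered gene ids (by decreasing |coefficient|, ties broken by
#'   gene id).
#' @slot weights matching elastic-net coefficients.
#' @slot provenance list: tuned hyperparameters, requested size, seed.
#' @exportClass ReducedPanel
setClass("ReducedPanel", representation(
  genes = "character", weights = "numeric", provenance = "list"
))

setValidity("ReducedPanel", function(object) {
  if (length(object@genes) != length(object@weights))
    return("genes and weights must align")
  TRUE
})

#' Proxy label assignment from marker-gene extremes
#'
#' @slot label per-sample factor: "positive-like", "negative-like",
#'   "excluded".
#' @slot proxyScore the per-sample proxy score the labels derive from.
#' @slot qLo,qHi quantile cutoffs used.
#' @exportClass ProxyLabelSet
setClass("ProxyLabelSet", representation(
  label = "factor", proxyScore = "numeric", qLo = "numeric", qHi = "numeric"
))

setValidity("ProxyLabelSet", function(object) {
  if (!all(levels(object@label) %in%
           c("positive-like", "negative-like", "excluded")))
    return("invalid label levels")
  TRUE
})

#' ROC result with available-case counts
#'
#' AUC is computed from ranks and satisfies AUC = U / (n_pos * n_neg), the
#' Mann-Whitney identity, with ties contributing 1/2.
#'
#' @slot auc area under the ROC curve in [0, 1].
#' @slot nPos,nNeg class counts after available-case filtering.
#' @slot operatingPoints data.frame of (threshold, tpr, fpr).
#' @exportClass ROCResult
setClass("ROCResult", representation(
  auc = "numeric", nPos = "integer", nNeg = "integer",
  operatingPoints = "data.frame"
))

setValidity("ROCResult", function(object) {
  if (!is.na(object@auc) && (object@auc < -1e-12 || object@auc > 1 + 1e-12))
    return("auc must lie in [0, 1]")
  TRUE
})
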