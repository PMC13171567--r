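#' Accessors for package result objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `responseValues()` returns the numeric matrix of a raw or standardized
#' response object, `cellLineIds()`/`drugIds()` its axes, `drugWeights()` the
#' reliability weights of a [DrugPanelQC-class], `scoreTable()` a data.frame
#' view of a [CompositeScoreTable-class] or [SignatureScoreTable-class],
#' `oofTable()` a data.frame view of an [OOFResult-class], and
#' `signatureGenes()` the up/down gene lists of a [SignatureModel-class].
#'
#' @param x the object.
#' @return `responseValues`: a numeric matrix; id accessors: character
#'   vectors; `scoreTable`/`oofTable`: data.frames; `drugWeights`: a named
#'   numeric vector; `signatureGenes`: a named list with elements `up` and
#'   `down`.
#' @name accessors
#' @aliases responseValues cellLineIds drugIds drugWeights scoreTable
#'   oofTable signatureGenes
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 30, nDrugs = 6, nGenes = 40, nSignatureGenes = 5, seed = 1))
#' dim(responseValues(sim$responses))
#' head(cellLineIds(sim$responses))
NULL

#' @rdname accessors
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))
#' @rdname accessors
#' @export
setGeneric("cellLineIds", function(x) standardGeneric("cellLineIds"))
#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("drugWeights", function(x) standardGeneric("drugWeights"))
#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setGeneric("oofTable", function(x) standardGeneric("oofTable"))
#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname accessors
setMethod("responseValues", "DrugResponseMatrix", function(x) x@values)
#' @rdname accessors
setMethod("responseValues", "StandardizedResponseMatrix", function(x) x@values)
#' @rdname accessors
setMethod("cellLineIds", "DrugResponseMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("cellLineIds", "StandardizedResponseMatrix",
          function(x) rownames(x@values))
#' @rdname accessors
setMethod("drugIds", "DrugResponseMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("drugIds", "StandardizedResponseMatrix",
          function(x) colnames(x@values))
#' @rdname accessors
setMethod("drugIds", "DrugPanelQC", function(x) names(x@coverage))
#' @rdname accessors
setMethod("drugWeights", "DrugPanelQC", function(x) x@weights)

#' @rdname accessors
setMethod("scoreTable", "CompositeScoreTable", function(x) {
  data.frame(cellLine = names(x@score), score = unname(x@score),
             weightedScore = unname(x@weightedScore),
             nDrugs = unname(x@nDrugs), weightSum = unname(x@weightSum),
             fallback = unname(x@fallback), row.names = NULL)
})

#' @rdname accessors
setMethod("scoreTable", "SignatureScoreTable", function(x) {
  data.frame(sample = x@sample, score = x@score, method = x@method,
             nGenesUsed = x@nGenesUsed, row.names = NULL)
})

#' @rdname accessors
setMethod("oofTable", "OOFResult", function(x) {
  data.frame(sample = names(x@observed), observed = unname(x@observed),
             predicted = unname(x@predicted), fold = unname(x@fold),
             row.names = NULL)
})

#' @rdname accessors
setMethod("signatureGenes", "SignatureModel",
          function(x) list(up = x@upGenes, down = x@downGenes))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCellLines, "cell lines,",
      object@nDrugs, "drugs,", object@nGenes, "genes (",
      object@nSignatureGenes, "planted ),",
      object@nLineages, "lineages; seed", object@seed, "\n")
})

setMethod("show", "DrugResponseMatrix", function(object) {
  v <- object@values
  cat("DrugResponseMatrix:", nrow(v), "cell lines x", ncol(v), "drugs;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(v))))
  if (length(object@qcLog)) cat("  QC:", object@qcLog[length(object@qcLog)], "\n")
})

setMethod("show", "StandardizedResponseMatrix", function(object) {
  cat("StandardizedResponseMatrix:", nrow(object@values), "cell lines x",
      ncol(object@values), "drugs; oriented =", object@oriented, "\n")
})

setMethod("show", "DrugPanelQC", function(object) {
  cat("DrugPanelQC:", length(object@coverage), "drugs; coverage",
      sprintf("[%.2f, %.2f];", min(object@coverage), max(object@coverage)),
      "weights", sprintf("[%.3f, %.3f]\n",
                         min(object@weights), max(object@weights)))
})

setMethod("show", "CompositeScoreTable", function(object) {
  cat("CompositeScoreTable:", length(object@score), "cell lines;",
      sum(is.na(object@score)), "unscored;",
      sum(object@fallback), "weight-fallback\n")
})

setMethod("show", "SplitHalfResult", function(object) {
  cat("SplitHalfResult:", length(object@rho), "repeats; median rho =",
      sprintf("%.3f", stats::median(object@rho)), "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan: K =", object@K, "folds over", length(object@fold),
      "samples (", length(unique(object@groups)), "groups )\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@family, "| grid:",
      paste(names(object@grid), lengths(object@grid), sep = "=",
            collapse = ", "),
      "| innerK =", object@innerK, "\n")
})

setMethod("show", "OOFResult", function(object) {
  rho <- spearman(object@predicted, object@observed)
  cat("OOFResult (", object@family, "):", length(object@observed),
      "samples,", length(object@foldModels), "folds; OOF Spearman rho =",
      sprintf("%.3f", rho), "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: rho_obs =", sprintf("%.3f", object@rhoObs),
      "; B =", length(object@rhoNull), "; p =",
      format(object@p, digits = 3), "\n")
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", length(object@upGenes), "up /",
      length(object@downGenes), "down genes (nTop =", object@nTop,
      ", stability >=", object@stabilityMin, ") from",
      ncol(object@foldWeights), "folds\n")
})

setMethod("show", "SignatureScoreTable", function(object) {
  cat("SignatureScoreTable (", object@method, "):", length(object@sample),
      "samples; score range",
      sprintf("[%.3f, %.3f]\n", min(object@score, na.rm = TRUE),
              max(object@score, na.rm = TRUE)))
})

setMethod("show", "ReducedPanel", function(object) {
  cat("ReducedPanel:", length(object@genes), "genes:",
      paste(utils::head(object@genes, 5), collapse = ", "),
      if (length(object@genes) > 5) "..." else "", "\n")
})

setMethod("show", "ProxyLabelSet", function(object) {
  tab <- table(object@label)
  cat("ProxyLabelSet (q =", object@qLo, "/", object@qHi, "):",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat("ROCResult: AUC =", sprintf("%.3f", object@auc),
      "( n_pos =", object@nPos, ", n_neg =", object@nNeg, ")\n")
})
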