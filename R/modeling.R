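#' Variance filter for expression features
#'
#' Removes genes whose standard deviation across all samples falls below
#' `minSd`. The filter never consults the outcome, so applying it once
#' globally (before fold splitting) is leakage-safe.
#'
#' @param expr genes x samples matrix (or SummarizedExperiment).
#' @param minSd non-negative SD threshold; 0 keeps everything.
#' @return the filtered matrix.
#' @examples
#' m <- rbind(const = rep(1, 5), varies = rnorm(5))
#' colnames(m) <- paste0("s", 1:5)
#' rownames(varianceFilter(m, 1e-6))
#' @export
varianceFilter <- function(expr, minSd = 1e-6) {
  expr <- exprMatrix(expr)
  if (minSd < 0) stop("minSd must be non-negative")
  sdv <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv >= minSd
  if (!any(keep)) stop("variance filter removed every gene")
  expr[keep, , drop = FALSE]
}

#' Build a group-aware cross-validation fold plan
#'
#' All samples sharing a group id land in the same fold (preventing
#' entity-level leakage); groups are shuffled deterministically by seed and
#' assigned greedily, largest group first, to the currently smallest fold, so
#' fold sizes are near-equal. With singleton groups this reduces to ordinary
#' K-fold splitting.
#'
#' @param groupIds character (or coercible) group id per sample.
#' @param K number of folds (default 5); must not exceed the number of
#'   distinct groups.
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @examples
#' makeFoldPlan(letters[1:10], K = 5, seed = 1)
#' @export
makeFoldPlan <- function(groupIds, K = 5L, seed = 1L) {
  groupIds <- as.character(groupIds)
  groups <- unique(groupIds)
  if (K > length(groups))
    stop("K (", K, ") exceeds the number of distinct groups (",
         length(groups), ")")
  sizes <- table(groupIds)[groups]
  withSeed(seed, {
    ord <- sample(length(groups))
    groupsShuffled <- groups[ord]
    sizesShuffled <- as.integer(sizes[ord])
    # largest first, ties kept in shuffled order, into the smallest fold
    bySize <- order(-sizesShuffled)
    foldLoad <- integer(K)
    groupFold <- integer(length(groups))
    names(groupFold) <- groupsShuffled[bySize]
    for (i in seq_along(bySize)) {
      k <- which.min(foldLoad)
      groupFold[i] <- k
      foldLoad[k] <- foldLoad[k] + sizesShuffled[bySize[i]]
    }
    new("FoldPlan", fold = unname(groupFold[groupIds]),
        groups = groupIds, K = as.integer(K), seed = as.integer(seed))
  })
}

#' Specify a model family and tuning grid
#'
#' Default grids: ridge penalty lambda in 10^\{-2..3\} (log-spaced, 6 values);
#' elastic net adds mixing alpha in \{0.1, 0.5, 0.9\}; SVR-RBF cost C in
#' \{0.1, 1, 10\} with kernel width gamma = median-heuristic x \{0.5, 1, 2\};
#' random forest uses 500 trees, unlimited depth, no tuned grid. Tuning
#' always maximizes the mean inner-fold Spearman correlation.
#'
#' @param family "ridge", "elastic_net", "svr_rbf" or "random_forest".
#' @param grid optional named list overriding the default candidate values.
#' @param innerK inner group-aware folds for hyperparameter tuning
#'   (default 3).
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec("ridge")
#' modelSpec("svr_rbf", grid = list(cost = c(1, 10), gammaScale = 1))
#' @export
modelSpec <- function(family = c("ridge", "elastic_net", "svr_rbf",
                                 "random_forest"),
                      grid = NULL, innerK = 3L) {
  family <- match.arg(family)
  default <- switch(family,
    ridge = list(lambda = 10^seq(-2, 3, length.out = 6)),
    elastic_net = list(alpha = c(0.1, 0.5, 0.9),
                       lambda = 10^seq(-2, 3, length.out = 6)),
    svr_rbf = list(cost = c(0.1, 1, 10), gammaScale = c(0.5, 1, 2)),
    random_forest = list(num.trees = 500))
  if (!is.null(grid)) default[names(grid)] <- grid
  new("ModelSpec", family = family, grid = default, innerK = as.integer(innerK))
}

# ---- internal model backends -----------------------------------------------

# Candidate table ordered so that ties on inner score resolve toward the
# least complex model (largest penalty / smallest cost), deterministically.
candidateGrid <- function(spec) {
  g <- spec@grid
  cand <- switch(spec@family,
    ridge = data.frame(lambda = sort(g$lambda, decreasing = TRUE)),
    elastic_net = expand.grid(lambda = sort(g$lambda, decreasing = TRUE),
                              alpha = sort(g$alpha)),
    svr_rbf = expand.grid(cost = sort(g$cost),
                          gammaScale = sort(g$gammaScale)),
    random_forest = data.frame(num.trees = g$num.trees[1]))
  cand
}

# median-heuristic RBF width on (already scaled) training features
medianHeuristicGamma <- function(X, seed) {
  n <- nrow(X)
  idx <- if (n > 200L) withSeed(seed, sample.int(n, 200L)) else seq_len(n)
  d2 <- stats::dist(X[idx, , drop = FALSE])^2
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) med <- 1
  1 / med
}

fitCandidate <- function(family, X, y, params, seed) {
  switch(family,
    ridge = glmnet::glmnet(X, y, alpha = 0, lambda = params$lambdaPath,
                           standardize = FALSE),
    elastic_net = glmnet::glmnet(X, y, alpha = params$alpha,
                                 lambda = params$lambdaPath,
                                 standardize = FALSE),
    svr_rbf = e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                         cost = params$cost, gamma = params$gamma,
                         scale = FALSE),
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = params$num.trees,
      seed = seed, num.threads = 1L))
}

predictCandidate <- function(family, fit, X, params = NULL) {
  switch(family,
    ridge = ,
    elastic_net = {
      idx <- match(TRUE, abs(fit$lambda - params$lambda) < 1e-12)
      if (!is.na(idx)) {
        as.numeric(X %*% fit$beta[, idx] + fit$a0[idx])
      } else {
        b <- as.numeric(stats::coef(fit, s = params$lambda))
        as.numeric(X %*% b[-1] + b[1])
      }
    },
    svr_rbf = as.numeric(stats::predict(fit, X)),
    random_forest = ranger::predictions(
      stats::predict(fit, data = as.data.frame(X), num.threads = 1L)))
}

coefCandidate <- function(family, fit, params, geneIds) {
  if (!family %in% c("ridge", "elastic_net")) return(NULL)
  cf <- as.numeric(stats::coef(fit, s = params$lambda))[-1]
  stats::setNames(cf, geneIds)
}

scaleTrain <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  # sample SD via moments; matches apply(X, 2, sd) to numerical tolerance
  scl <- sqrt(pmax(colSums(X^2) - n * center^2, 0) / (n - 1))
  keep <- is.finite(scl) & scl > 0
  list(center = center[keep], scale = scl[keep], genes = colnames(X)[keep])
}

applyScale <- function(X, sc) {
  sweep(sweep(X[, sc$genes, drop = FALSE], 2L, sc$center, "-"),
        2L, sc$scale, "/")
}

# Inner group-aware tuning on the training split only. Returns the selected
# row of the candidate grid. With a single candidate the search is skipped.
tuneInner <- function(Xtr, ytr, groupsTr, spec, seed) {
  cand <- candidateGrid(spec)
  if (nrow(cand) == 1L) return(cand[1L, , drop = FALSE])
  innerPlan <- makeFoldPlan(groupsTr, K = spec@innerK, seed = seed)
  lambdaPath <- if (spec@family %in% c("ridge", "elastic_net"))
    sort(spec@grid$lambda, decreasing = TRUE) else NULL
  scores <- matrix(NA_real_, nrow(cand), spec@innerK)
  for (k in seq_len(spec@innerK)) {
    trIdx <- innerPlan@fold != k
    if (sum(trIdx) < 3L || sum(!trIdx) < 2L)
      stop("inner CV infeasible: too few groups in inner fold ", k)
    sc <- scaleTrain(Xtr[trIdx, , drop = FALSE])
    Xi <- applyScale(Xtr[trIdx, , drop = FALSE], sc)
    Xv <- applyScale(Xtr[!trIdx, , drop = FALSE], sc)
    yi <- ytr[trIdx]
    if (spec@family %in% c("ridge", "elastic_net")) {
      # one path fit per alpha serves every lambda candidate
      for (al in unique(if (is.null(cand$alpha)) 0 else cand$alpha)) {
        fit <- fitCandidate(spec@family, Xi, yi,
                            list(alpha = al, lambdaPath = lambdaPath),
                            seed)
        rows <- if (is.null(cand$alpha)) seq_len(nrow(cand))
                else which(cand$alpha == al)
        for (r in rows) {
          pred <- predictCandidate(spec@family, fit, Xv,
                                   list(lambda = cand$lambda[r]))
          scores[r, k] <- spearman(pred, ytr[!trIdx])
        }
      }
    } else {
      gamma0 <- if (spec@family == "svr_rbf")
        medianHeuristicGamma(Xi, seed) else NULL
      for (r in seq_len(nrow(cand))) {
        params <- as.list(cand[r, , drop = FALSE])
        if (spec@family == "svr_rbf")
          params$gamma <- gamma0 * params$gammaScale
        fit <- fitCandidate(spec@family, Xi, yi, params, seed)
        pred <- predictCandidate(spec@family, fit, Xv, params)
        scores[r, k] <- spearman(pred, ytr[!trIdx])
      }
    }
  }
  meanScore <- rowMeans(scores)
  meanScore[is.na(meanScore)] <- -Inf
  cand[which.max(meanScore), , drop = FALSE]
}

#' Fit models fold-wise and assemble out-of-fold predictions
#'
#' The leakage-safe harness: for each outer fold k, per-gene scaling
#' parameters are estimated on the training split only and applied verbatim
#' to the held-out fold (training-fold SD-0 genes are dropped for that fold);
#' hyperparameters are selected by inner group-aware cross-validation on the
#' training split only, maximizing mean inner Spearman (ties resolve toward
#' the least complex candidate); the tuned model is refit on the full
#' training split and predicts fold k. The concatenated predictions form the
#' OOF vector: every sample predicted exactly once, by a model that never saw
#' it. For linear families the per-fold coefficients (standardized-feature
#' scale) are retained for signature derivation.
#'
#' @param expr genes x samples matrix (samples must cover the plan).
#' @param y named numeric outcome (composite scores); no missing values among
#'   plan samples.
#' @param plan a [FoldPlan-class] over the samples.
#' @param spec a [ModelSpec-class].
#' @param seed integer seed (inner fold splits, forest seeds).
#' @param fixedParams optional list of per-fold hyperparameter rows; when
#'   supplied the inner search is skipped (used to freeze tuning inside
#'   permutation runs).
#' @return an [OOFResult-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 60, nSignatureGenes = 8, seed = 9))
#' z <- standardizeAndOrient(sim$responses)
#' qc <- computeWeights(pairwiseConcordance(z, minOverlap = 10))
#' y <- compositeScores(z, qc)@weightedScore
#' plan <- makeFoldPlan(names(y), K = 3, seed = 1)
#' oof <- fitPredictOOF(sim$expression, y, plan,
#'                      modelSpec("ridge"), seed = 1)
#' oof
#' @export
fitPredictOOF <- function(expr, y, plan, spec = modelSpec("ridge"),
                          seed = 1L, fixedParams = NULL) {
  expr <- exprMatrix(expr)
  stopifnot(is(plan, "FoldPlan"), is(spec, "ModelSpec"))
  samples <- names(y)
  if (is.null(samples)) stop("y must be named by sample id")
  if (!all(samples %in% colnames(expr)))
    stop("expression matrix lacks some plan samples")
  if (length(y) != length(plan@fold))
    stop("y and fold plan must align")
  if (anyNA(y)) stop("missing y among plan samples")
  X <- t(expr[, samples, drop = FALSE])
  predicted <- stats::setNames(rep(NA_real_, length(y)), samples)
  foldModels <- vector("list", plan@K)
  lambdaPath <- if (spec@family %in% c("ridge", "elastic_net"))
    sort(spec@grid$lambda, decreasing = TRUE) else NULL
  for (k in seq_len(plan@K)) {
    tr <- plan@fold != k
    te <- !tr
    if (!any(te)) {
      foldModels[[k]] <- list(params = NULL, center = NULL, scale = NULL,
                              genes = character(0), coefficients = NULL)
      next
    }
    foldSeed <- stageSeed(seed, paste0("fold", k))
    params <- if (!is.null(fixedParams)) fixedParams[[k]]
              else tuneInner(X[tr, , drop = FALSE], y[tr],
                             plan@groups[tr], spec, foldSeed)
    sc <- scaleTrain(X[tr, , drop = FALSE])
    Xtr <- applyScale(X[tr, , drop = FALSE], sc)
    Xte <- applyScale(X[te, , drop = FALSE], sc)
    p <- as.list(params)
    p$lambdaPath <- lambdaPath
    if (spec@family == "svr_rbf")
      p$gamma <- medianHeuristicGamma(Xtr, foldSeed) * p$gammaScale
    fit <- fitCandidate(spec@family, Xtr, y[tr], p, foldSeed)
    predicted[te] <- predictCandidate(spec@family, fit, Xte, p)
    foldModels[[k]] <- list(
      params = params, center = sc$center, scale = sc$scale,
      genes = sc$genes,
      coefficients = coefCandidate(spec@family, fit, p, sc$genes))
  }
  new("OOFResult", observed = y, predicted = predicted,
      fold = plan@fold, foldModels = foldModels, family = spec@family,
      seed = as.integer(seed))
}

#' Evaluate out-of-fold performance
#'
#' Spearman rank correlation between observed outcomes and the concatenated
#' OOF predictions, with asymptotic two-sided p. Constant predictions leave
#' the statistic undefined (returned as NA with a status, not an error).
#'
#' @param oof an [OOFResult-class] with >= 3 samples.
#' @return list with `rho`, `p`, `n`, `status`.
#' @examples
#' oof <- new("OOFResult",
#'   observed = c(a = 1, b = 2, c = 3, d = 4, e = 5),
#'   predicted = c(a = 1, b = 2, c = 3, d = 5, e = 4),
#'   fold = rep(1:5, 1), foldModels = list(), family = "ridge", seed = 1L)
#' evaluateOOF(oof)$rho  # 0.9
#' @export
evaluateOOF <- function(oof) {
  stopifnot(is(oof, "OOFResult"))
  if (length(oof@observed) < 3L) stop("need at least 3 samples")
  if (stats::sd(oof@predicted, na.rm = TRUE) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(oof@observed),
                status = "constant predictions"))
  st <- spearmanTest(oof@predicted, oof@observed)
  c(st, list(status = "ok"))
}

#' Permutation test of out-of-fold performance
#'
#' Shuffles the outcome across cell lines B times, re-runs the full
#' leakage-safe pipeline (including inner tuning, unless `retune = FALSE`
#' freezes the observed fold hyperparameters for speed) for each permutation,
#' and reports the one-sided empirical p-value
#' p = (1 + #\{rho_b >= rho_obs\}) / (B + 1), bounded below by 1/(B+1).
#'
#' @param expr genes x samples matrix.
#' @param y named outcome vector.
#' @param plan a [FoldPlan-class].
#' @param spec a [ModelSpec-class].
#' @param B number of permutations (>= 1; the study-scale default is 5000,
#'   but smaller B gives valid, coarser p-values).
#' @param seed integer seed (drives the permutations and all refits).
#' @param retune re-run the inner hyperparameter search per permutation
#'   (TRUE, the default) or freeze the observed tuned values (FALSE).
#' @return a [PermutationResult-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 40, nDrugs = 6, nGenes = 30, nSignatureGenes = 5, seed = 2))
#' z <- standardizeAndOrient(sim$responses)
#' y <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 5)))@weightedScore
#' plan <- makeFoldPlan(names(y), K = 3, seed = 1)
#' permutationTest(sim$expression, y, plan,
#'                 modelSpec("ridge", grid = list(lambda = 10)),
#'                 B = 19, seed = 1)
#' @export
permutationTest <- function(expr, y, plan, spec = modelSpec("ridge"),
                            B = 5000L, seed = 1L, retune = TRUE) {
  if (B < 1L) stop("B must be at least 1")
  expr <- exprMatrix(expr)
  oof <- fitPredictOOF(expr, y, plan, spec, seed = seed)
  rhoObs <- spearman(oof@predicted, oof@observed)
  fixed <- if (retune) NULL else lapply(oof@foldModels, `[[`, "params")
  rhoNull <- withSeed(stageSeed(seed, "perm"), {
    vapply(seq_len(B), function(b) {
      yb <- stats::setNames(sample(unname(y)), names(y))
      oofB <- fitPredictOOF(expr, yb, plan, spec,
                            seed = stageSeed(seed, paste0("permfit", b)),
                            fixedParams = fixed)
      spearman(oofB@predicted, oofB@observed)
    }, numeric(1))
  })
  p <- (1 + sum(rhoNull >= rhoObs)) / (B + 1)
  new("PermutationResult", rhoObs = rhoObs, rhoNull = rhoNull, p = p,
      seed = as.integer(seed))
}

#' Residual and calibration diagnostics from OOF predictions
#'
#' Residuals are observed minus predicted; the calibration table bins samples
#' into equal-frequency bins on the predicted score and reports per bin the
#' sample count, mean prediction, mean observed value and its SEM.
#'
#' @param oof an [OOFResult-class].
#' @param nBins number of equal-frequency bins (>= 2, default 10; needs at
#'   least `nBins` samples).
#' @return list: `residuals` (named), `residualVsPredicted` (data.frame),
#'   `calibration` (data.frame with n, meanPredicted, meanObserved, sem).
#' @examples
#' oof <- new("OOFResult",
#'   observed = setNames(rnorm(40), paste0("s", 1:40)),
#'   predicted = setNames(rnorm(40), paste0("s", 1:40)),
#'   fold = rep(1:4, 10), foldModels = list(), family = "ridge", seed = 1L)
#' residualDiagnostics(oof, nBins = 4)$calibration
#' @export
residualDiagnostics <- function(oof, nBins = 10L) {
  stopifnot(is(oof, "OOFResult"))
  n <- length(oof@observed)
  if (nBins < 2L) stop("nBins must be at least 2")
  if (n < nBins) stop("need at least nBins samples")
  res <- oof@observed - oof@predicted
  ord <- rank(oof@predicted, ties.method = "first")
  bin <- ceiling(ord * nBins / n)
  calib <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    idx <- bin == b
    yo <- oof@observed[idx]
    data.frame(bin = b, n = sum(idx),
               meanPredicted = mean(oof@predicted[idx]),
               meanObserved = mean(yo),
               sem = stats::sd(yo) / sqrt(sum(idx)))
  }))
  list(residuals = res,
       residualVsPredicted = data.frame(predicted = unname(oof@predicted),
                                        residual = unname(res)),
       calibration = calib)
}

#' Post-hoc marker-stratified OOF performance
#'
#' Strata are defined after the fact from baseline expression of marker
#' genes (e.g. receptor-family members): the "high" stratum is samples whose
#' mean marker expression is at or above the given quantile cutoff.
#' Performance is recomputed on each stratum's existing OOF predictions --
#' no refitting -- so leakage control is preserved.
#'
#' @param oof an [OOFResult-class].
#' @param expr genes x samples matrix containing the marker genes.
#' @param markerGenes character vector of marker gene ids.
#' @param quartile quantile cutoff for the high stratum (default 0.75).
#' @return data.frame with rows all / markerHigh / markerLow: rho, p, n
#'   (rho is NA for strata with fewer than 5 samples).
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 60, nSignatureGenes = 8, seed = 9))
#' z <- standardizeAndOrient(sim$responses)
#' y <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 10)))@weightedScore
#' plan <- makeFoldPlan(names(y), K = 3, seed = 1)
#' oof <- fitPredictOOF(sim$expression, y, plan, modelSpec("ridge"), seed = 1)
#' stratifiedOOFPerformance(oof, sim$expression, c("FGFR1", "FGFR2"))
#' @export
stratifiedOOFPerformance <- function(oof, expr, markerGenes,
                                     quartile = 0.75) {
  stopifnot(is(oof, "OOFResult"))
  expr <- exprMatrix(expr)
  missing <- setdiff(markerGenes, rownames(expr))
  if (length(missing))
    stop("marker gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  samples <- names(oof@observed)
  marker <- colMeans(expr[markerGenes, samples, drop = FALSE])
  cutoff <- quantileCut(marker, quartile)
  strata <- list(all = rep(TRUE, length(samples)),
                 markerHigh = marker >= cutoff,
                 markerLow = marker < cutoff)
  do.call(rbind, lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (sum(idx) < 5L)
      return(data.frame(stratum = nm, rho = NA_real_, p = NA_real_,
                        n = sum(idx)))
    st <- spearmanTest(oof@predicted[idx], oof@observed[idx])
    data.frame(stratum = nm, rho = st$rho, p = st$p, n = st$n)
  }))
}

#' Leave-one-lineage-out sensitivity refit
#'
#' Refits the ridge track with one lineage excluded and quantifies how much
#' the learned program moves: Spearman correlation between the fold-averaged
#' coefficient vectors of the full and reduced fits, and (when a reference
#' cohort is supplied) between projected up-down signature scores on that
#' cohort.
#'
#' @param expr genes x samples matrix.
#' @param y named outcome vector.
#' @param lineages factor of lineage labels aligned with `y`.
#' @param exclude lineage label to hold out (may be absent from the data, in
#'   which case the refit is identical by construction).
#' @param K outer folds (default 5).
#' @param seed integer seed.
#' @param spec a linear-family [ModelSpec-class] (default ridge).
#' @param cohort optional genes x samples reference cohort for projected
#'   score concordance.
#' @param nTop,stabilityMin signature selection parameters for the projected
#'   comparison.
#' @return list: `coefRho`, `scoreRho` (NA without a cohort), `nExcluded`.
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 60, nSignatureGenes = 8, seed = 9))
#' z <- standardizeAndOrient(sim$responses)
#' y <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 10)))@weightedScore
#' leaveGroupOutRefit(sim$expression, y, sim$lineages,
#'                    exclude = levels(sim$lineages)[1], K = 3, seed = 1)
#' @export
leaveGroupOutRefit <- function(expr, y, lineages, exclude, K = 5L,
                               seed = 1L, spec = modelSpec("ridge"),
                               cohort = NULL, nTop = 25L,
                               stabilityMin = 0.8) {
  expr <- exprMatrix(expr)
  lineages <- as.factor(lineages)
  if (length(lineages) != length(y)) stop("lineages must align with y")
  keep <- lineages != exclude
  nExcluded <- sum(!keep)
  if (nExcluded == length(y)) stop("cannot exclude the whole panel")
  if (nExcluded > length(y) / 2)
    warning("excluding more than 50% of lines")
  avgCoef <- function(oof) {
    cf <- lapply(oof@foldModels, `[[`, "coefficients")
    cf <- cf[!vapply(cf, is.null, logical(1))]
    genes <- Reduce(intersect, lapply(cf, names))
    rowMeans(vapply(cf, function(x) x[genes], numeric(length(genes))))
  }
  runFit <- function(idx) {
    ysub <- y[idx]
    plan <- makeFoldPlan(names(ysub), K = K, seed = seed)
    fitPredictOOF(expr[, names(ysub), drop = FALSE], ysub, plan, spec,
                  seed = seed)
  }
  oofFull <- runFit(rep(TRUE, length(y)))
  oofRed <- if (nExcluded == 0L) oofFull else runFit(keep)
  cfFull <- avgCoef(oofFull)
  cfRed <- avgCoef(oofRed)
  genes <- intersect(names(cfFull), names(cfRed))
  coefRho <- spearman(cfFull[genes], cfRed[genes])
  scoreRho <- NA_real_
  if (!is.null(cohort)) {
    sigF <- deriveSignature(foldCoefficients(oofFull), nTop = nTop,
                            stabilityMin = stabilityMin)
    sigR <- deriveSignature(foldCoefficients(oofRed), nTop = nTop,
                            stabilityMin = stabilityMin)
    scoreRho <- scoreConcordance(updownScore(cohort, sigF),
                                 updownScore(cohort, sigR))$rho
  }
  list(coefRho = coefRho, scoreRho = scoreRho, nExcluded = nExcluded)
}

#' Extract per-fold coefficient matrix from an OOF fit
#'
#' Convenience bridge from the modeling harness to signature derivation:
#' collects the per-fold linear coefficients (standardized-feature scale)
#' over the genes common to all folds.
#'
#' @param oof an [OOFResult-class] from a linear family.
#' @return genes x folds numeric matrix.
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 60, nSignatureGenes = 8, seed = 9))
#' z <- standardizeAndOrient(sim$responses)
#' y <- compositeScores(z, computeWeights(
#'   pairwiseConcordance(z, minOverlap = 10)))@weightedScore
#' plan <- makeFoldPlan(names(y), K = 3, seed = 1)
#' oof <- fitPredictOOF(sim$expression, y, plan, modelSpec("ridge"), seed = 1)
#' dim(foldCoefficients(oof))
#' @export
foldCoefficients <- function(oof) {
  stopifnot(is(oof, "OOFResult"))
  cf <- lapply(oof@foldModels, `[[`, "coefficients")
  cf <- cf[!vapply(cf, is.null, logical(1))]
  if (length(cf) < 2L)
    stop("need linear-family coefficients from at least 2 folds")
  genes <- Reduce(intersect, lapply(cf, names))
  out <- vapply(cf, function(x) x[genes], numeric(length(genes)))
  rownames(out) <- genes
  out
}
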