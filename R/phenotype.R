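#' Filter drugs by measurement coverage
#'
#' Coverage of drug d is c_d = n_d / N, the fraction of profiled cell lines
#' with an observed response. Drugs with c_d below the threshold are dropped
#' (they destabilize concordance estimates and inflate missingness-driven
#' variance in the composites); exclusions are appended to the object's QC
#' log.
#'
#' @param raw a [DrugResponseMatrix-class].
#' @param minCoverage retention threshold in (0, 1]; drugs with
#'   c_d >= minCoverage are kept. Default 0.8.
#' @return the filtered [DrugResponseMatrix-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 60, nDrugs = 8, nGenes = 20, nSignatureGenes = 4,
#'   missingRate = 0.25, seed = 2))
#' filterDrugsByCoverage(sim$responses, minCoverage = 0.8)
#' @export
filterDrugsByCoverage <- function(raw, minCoverage = 0.8) {
  stopifnot(is(raw, "DrugResponseMatrix"))
  if (minCoverage <= 0 || minCoverage > 1)
    stop("minCoverage must lie in (0, 1]")
  v <- raw@values
  cov <- colSums(!is.na(v)) / nrow(v)
  keep <- cov >= minCoverage
  if (!any(keep)) stop("no drug meets the coverage threshold; empty panel")
  dropped <- colnames(v)[!keep]
  log <- sprintf("coverage filter (>= %g): retained %d/%d drugs%s",
                 minCoverage, sum(keep), length(keep),
                 if (length(dropped))
                   paste0("; excluded ", paste(dropped, collapse = ", "))
                 else "")
  new("DrugResponseMatrix", values = v[, keep, drop = FALSE],
      qcLog = c(raw@qcLog, log))
}

#' Standardize per drug and orient toward sensitivity
#'
#' Within each drug, responses are z-scored across cell lines over
#' non-missing entries (sample-SD convention) and multiplied by -1, so that
#' larger standardized values consistently indicate higher sensitivity (raw
#' log2 fold-change viability is more negative for stronger inhibition):
#' z_{i,d} = -(r_{i,d} - mu_d) / sigma_d. Missing entries stay missing.
#'
#' @param raw a [DrugResponseMatrix-class]; every drug needs >= 2 non-missing
#'   values and non-zero spread.
#' @return a [StandardizedResponseMatrix-class] retaining per-drug mu_d and
#'   sigma_d.
#' @examples
#' m <- matrix(c(-2, 0, 2, 1, 3, 5), nrow = 3,
#'             dimnames = list(paste0("cl", 1:3), c("dA", "dB")))
#' z <- standardizeAndOrient(new("DrugResponseMatrix", values = m,
#'                               qcLog = character(0)))
#' responseValues(z)
#' @export
standardizeAndOrient <- function(raw) {
  stopifnot(is(raw, "DrugResponseMatrix"))
  v <- raw@values
  mu <- colMeans(v, na.rm = TRUE)
  sigma <- apply(v, 2L, stats::sd, na.rm = TRUE)
  bad <- which(is.na(sigma) | sigma == 0)
  if (length(bad))
    stop("constant response for drug(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  z <- -sweep(sweep(v, 2L, mu, "-"), 2L, sigma, "/")
  new("StandardizedResponseMatrix", values = z, mu = mu, sigma = sigma,
      oriented = TRUE)
}

#' Pairwise drug-drug concordance and panel coverage
#'
#' For every drug pair, Spearman correlation of oriented z-scores over the
#' cell lines measured for both drugs; pairs with fewer than `minOverlap`
#' shared lines are recorded as missing and excluded from each drug's mean
#' concordance rho-bar_d (the average of its available off-diagonal entries).
#' A drug with no valid pair gets rho-bar_d = NA, which downstream maps to
#' weight 0.
#'
#' @param z a [StandardizedResponseMatrix-class].
#' @param minOverlap minimum number of jointly measured lines for a pair to
#'   count (>= 3; default 20).
#' @return a [DrugPanelQC-class] with coverage, concordance and overlap
#'   populated; weights are filled by [computeWeights()].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 80, nDrugs = 6, nGenes = 20, nSignatureGenes = 4, seed = 4))
#' qc <- pairwiseConcordance(standardizeAndOrient(sim$responses))
#' qc
#' @export
pairwiseConcordance <- function(z, minOverlap = 20L) {
  stopifnot(is(z, "StandardizedResponseMatrix"))
  if (minOverlap < 3L) stop("minOverlap must be at least 3")
  v <- z@values
  D <- ncol(v)
  obs <- !is.na(v)
  overlap <- crossprod(obs)
  conc <- matrix(NA_real_, D, D, dimnames = dimnames(overlap))
  diag(conc) <- 1
  for (a in seq_len(D - 1L)) {
    for (b in seq.int(a + 1L, D)) {
      if (overlap[a, b] >= minOverlap) {
        conc[a, b] <- conc[b, a] <- spearman(v[, a], v[, b])
      }
    }
  }
  rbar <- vapply(seq_len(D), function(d) {
    off <- conc[d, -d]
    if (all(is.na(off))) NA_real_ else mean(off, na.rm = TRUE)
  }, numeric(1))
  names(rbar) <- colnames(v)
  cov <- colSums(obs) / nrow(v)
  new("DrugPanelQC", coverage = cov, meanConcordance = rbar,
      weights = stats::setNames(rep(NA_real_, D), colnames(v)),
      concordance = conc, overlap = overlap,
      minOverlap = as.integer(minOverlap))
}

#' Compute drug reliability weights
#'
#' w_d = c_d * max(0, rho-bar_d): a drug is down-weighted in proportion to
#' its missingness and contributes nothing when it is uncorrelated or
#' anti-correlated with the rest of the panel. Missing rho-bar_d (no valid
#' pair) gives weight 0.
#'
#' @param qc a [DrugPanelQC-class] from [pairwiseConcordance()].
#' @return the same object with the `weights` slot filled.
#' @examples
#' qc <- new("DrugPanelQC",
#'   coverage = c(dA = 1, dB = 0.5),
#'   meanConcordance = c(dA = 0.4, dB = -0.2),
#'   weights = c(dA = NA_real_, dB = NA_real_),
#'   concordance = diag(2), overlap = matrix(3, 2, 2), minOverlap = 3L)
#' drugWeights(computeWeights(qc))  # 0.4, 0
#' @export
computeWeights <- function(qc) {
  stopifnot(is(qc, "DrugPanelQC"))
  rbar <- qc@meanConcordance
  rbar[is.na(rbar)] <- 0
  qc@weights <- qc@coverage * pmax(0, rbar)
  validObject(qc)
  qc
}

#' Composite sensitivity scores per cell line
#'
#' For each line i with measured drug set D_i: the unweighted composite
#' S_i = mean of z_{i,d} over D_i, and the weighted composite
#' S_i^w = sum(w_d z_{i,d}) / sum(w_d) over D_i, i.e. with reliability
#' weights renormalized to sum 1 within each line's available drug set.
#' Lines whose available weights sum to 0 fall back to the unweighted score
#' (with a warning); lines with no measured drug get NA.
#'
#' @param z a [StandardizedResponseMatrix-class].
#' @param qc a [DrugPanelQC-class] with weights computed.
#' @return a [CompositeScoreTable-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 80, nDrugs = 6, nGenes = 20, nSignatureGenes = 4, seed = 4))
#' z <- standardizeAndOrient(sim$responses)
#' qc <- computeWeights(pairwiseConcordance(z))
#' compositeScores(z, qc)
#' @export
compositeScores <- function(z, qc) {
  stopifnot(is(z, "StandardizedResponseMatrix"), is(qc, "DrugPanelQC"))
  v <- z@values
  if (!identical(colnames(v), names(qc@weights)))
    stop("drug panels of z and qc disagree")
  w <- qc@weights
  n <- nrow(v)
  S <- Sw <- wsum <- rep(NA_real_, n)
  nD <- integer(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    ok <- !is.na(v[i, ])
    nD[i] <- sum(ok)
    if (nD[i] == 0L) next
    zi <- v[i, ok]
    S[i] <- mean(zi)
    wi <- w[ok]
    wsum[i] <- sum(wi)
    if (wsum[i] > 0) {
      Sw[i] <- sum(wi * zi) / wsum[i]
    } else {
      Sw[i] <- S[i]
      fallback[i] <- TRUE
    }
  }
  if (any(fallback))
    warning(sum(fallback), " line(s) had zero total weight; ",
            "weighted score fell back to unweighted")
  ids <- rownames(v)
  new("CompositeScoreTable",
      score = stats::setNames(S, ids),
      weightedScore = stats::setNames(Sw, ids),
      nDrugs = stats::setNames(nD, ids),
      weightSum = stats::setNames(wsum, ids),
      fallback = stats::setNames(fallback, ids))
}

#' Split-half reliability of the composite phenotype
#'
#' Repeatedly partitions the retained drug panel into two random disjoint
#' halves (sizes differing by at most one), recomputes the unweighted
#' composite per half, and correlates the two half-scores (Spearman) over
#' lines with both halves measured. The median over repeats is an empirical
#' ceiling on how predictable the phenotype can be.
#'
#' @param z a [StandardizedResponseMatrix-class] with >= 4 drugs.
#' @param nRepeats number of random splits (default 200).
#' @param seed integer seed (determines the half assignments exactly).
#' @param weighted if TRUE, half-scores use reliability weights recomputed
#'   within each half; default FALSE (unweighted halves).
#' @param minOverlap passed to [pairwiseConcordance()] when `weighted`.
#' @return a [SplitHalfResult-class]; repeats with fewer than 3 doubly scored
#'   lines are skipped and counted.
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 100, nDrugs = 12, nGenes = 20, nSignatureGenes = 4,
#'   seed = 5))
#' splitHalfReliability(standardizeAndOrient(sim$responses),
#'                      nRepeats = 25, seed = 1)
#' @export
splitHalfReliability <- function(z, nRepeats = 200L, seed = 1L,
                                 weighted = FALSE, minOverlap = 20L) {
  stopifnot(is(z, "StandardizedResponseMatrix"))
  v <- z@values
  D <- ncol(v)
  if (D < 4L) stop("split-half reliability needs at least 4 retained drugs")
  halfScore <- function(cols) {
    # columns are already oriented z-scores; aggregate directly
    zz <- v[, cols, drop = FALSE]
    if (weighted) {
      mu <- colMeans(zz, na.rm = TRUE)
      sig <- apply(zz, 2L, stats::sd, na.rm = TRUE)
      zs <- new("StandardizedResponseMatrix",
                values = sweep(sweep(zz, 2L, mu, "-"), 2L, sig, "/"),
                mu = mu, sigma = sig, oriented = TRUE)
      qc <- computeWeights(pairwiseConcordance(zs, minOverlap = minOverlap))
      compositeScores(zs, qc)@weightedScore
    } else {
      rowMeans(zz, na.rm = TRUE)
    }
  }
  withSeed(seed, {
    rho <- numeric(0)
    assignments <- list()
    skipped <- 0L
    for (b in seq_len(nRepeats)) {
      half <- sample(rep(c(TRUE, FALSE), length.out = D))
      sA <- suppressWarnings(halfScore(which(half)))
      sB <- suppressWarnings(halfScore(which(!half)))
      ok <- is.finite(sA) & is.finite(sB)
      if (sum(ok) < 3L) {
        skipped <- skipped + 1L
        next
      }
      rho <- c(rho, spearman(sA[ok], sB[ok]))
      assignments[[length(assignments) + 1L]] <- half
    }
    new("SplitHalfResult", rho = rho, assignments = assignments,
        seed = as.integer(seed), skipped = skipped)
  })
}

#' Per-line variability across the drug panel
#'
#' Sample standard deviation of each cell line's oriented z-scores across its
#' measured drugs; NA for lines with fewer than 2 measured drugs. Large
#' values flag lines that respond inconsistently across the inhibitor class.
#'
#' @param z a [StandardizedResponseMatrix-class].
#' @return named numeric vector of per-line SDs.
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 50, nDrugs = 8, nGenes = 20, nSignatureGenes = 4, seed = 6))
#' summary(crossDrugVariability(standardizeAndOrient(sim$responses)))
#' @export
crossDrugVariability <- function(z) {
  stopifnot(is(z, "StandardizedResponseMatrix"))
  v <- z@values
  out <- apply(v, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  })
  stats::setNames(out, rownames(v))
}

#' Coverage-confound diagnostic for the composite score
#'
#' Negative control: under missingness unrelated to sensitivity, the weighted
#' composite must not track how many drugs a line happened to be measured on.
#' Reports Spearman correlation (asymptotic two-sided p) between S_i^w and
#' |D_i|. When every line has the same drug count the statistic is undefined
#' and a status is returned instead of an error.
#'
#' @param scores a [CompositeScoreTable-class] (>= 3 scored lines).
#' @return list with `rho`, `p`, `n`, `status` ("ok" or
#'   "constant coverage").
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(
#'   nCellLines = 100, nDrugs = 10, nGenes = 20, nSignatureGenes = 4,
#'   missingRate = 0.2, seed = 6))
#' z <- standardizeAndOrient(sim$responses)
#' qc <- computeWeights(pairwiseConcordance(z))
#' coverageConfoundCheck(compositeScores(z, qc))
#' @export
coverageConfoundCheck <- function(scores) {
  stopifnot(is(scores, "CompositeScoreTable"))
  ok <- !is.na(scores@weightedScore)
  if (sum(ok) < 3L) stop("need at least 3 scored lines")
  nD <- scores@nDrugs[ok]
  if (length(unique(nD)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok),
                status = "constant coverage"))
  st <- spearmanTest(scores@weightedScore[ok], as.numeric(nD))
  list(rho = st$rho, p = st$p, n = st$n, status = "ok")
}
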