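#' Read a numeric matrix from TSV/CSV or GCT
#'
#' TSV/CSV files need a header row and ids in the first column; GCT v1.2
#' files (detected by a leading `#1.2`) are accepted for expression, with the
#' Description column dropped. Duplicate row ids are collapsed by mean with a
#' warning; duplicate column ids are an error. Empty strings and `NA` tokens
#' become missing values.
#'
#' @param path file path (.tsv/.txt, .csv, or .gct).
#' @param orientation "genes" (rows are genes; the default) or "samples"
#'   (rows are samples/cell lines) -- informational, recorded as an
#'   attribute.
#' @return numeric matrix with dimnames; attribute `orientation` set.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeMatrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
#'                                            c("s1", "s2"))), f)
#' readMatrix(f)
#' @export
readMatrix <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  isGct <- startsWith(first, "#1.2")
  if (isGct) {
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- df[[1]]
    df <- df[, -c(1L, 2L), drop = FALSE]  # drop Name, Description
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    header <- strsplit(first, sep, fixed = TRUE)[[1]][-1]
    if (anyDuplicated(header))
      stop("duplicate sample ids in ", path, ": ",
           paste(unique(header[duplicated(header)]), collapse = ", "))
    df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    ids <- df[[1]]
    df <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(colnames(df)))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(df)[duplicated(colnames(df))]),
               collapse = ", "))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric column '", colnames(df)[bad], "' in ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("collapsing ", length(dup), " duplicated row id(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "))
    m <- rowsum(m, group = ids, na.rm = TRUE) /
      as.vector(table(ids)[sort(unique(ids))])
    ids <- rownames(m)
  }
  rownames(m) <- ids
  attr(m, "orientation") <- orientation
  m
}

#' Write a numeric matrix as TSV
#'
#' Row ids go into a first `id` column; values are written with full
#' precision (15 significant digits) so write/read round-trips and manifest
#' hashes are stable.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatrix <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, function(x) format(x, digits = 15,
                                                   trim = TRUE)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Collects the tunables of every stage plus stage toggles into a plain list
#' that round-trips through JSON unchanged; every [runPipeline()] run writes
#' a config echo alongside its outputs.
#'
#' @param simulation a [SimulationConfig-class] (its seed is overridden by
#'   `seed`).
#' @param stages character subset of c("simulate", "phenotype", "train",
#'   "signature", "project").
#' @param minCoverage,minOverlap phenotype-stage thresholds.
#' @param splitHalfRepeats split-half repeats.
#' @param K,innerK outer/inner fold counts.
#' @param model model family for the predictive track.
#' @param ridgeLambda ridge grid for the signature track.
#' @param B permutation count (0 disables the permutation stage).
#' @param nTop,stabilityMin signature selection parameters.
#' @param ssgseaAlpha ssGSEA exponent.
#' @param panelSize reduced-panel size.
#' @param qLo,qHi proxy-label quantiles.
#' @param seed master seed; each stage derives its own stream from it.
#' @return a list of class "fgfriPipelineConfig".
#' @examples
#' cfg <- pipelineConfig(simulationConfig(nCellLines = 60, nDrugs = 8,
#'                                        nGenes = 80, nSignatureGenes = 8),
#'                       seed = 11)
#' names(cfg)
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           stages = c("simulate", "phenotype", "train",
                                      "signature", "project"),
                           minCoverage = 0.8, minOverlap = 20L,
                           splitHalfRepeats = 200L,
                           K = 5L, innerK = 3L,
                           model = "ridge",
                           ridgeLambda = 10^seq(-2, 3, length.out = 6),
                           B = 0L,
                           nTop = 25L, stabilityMin = 0.8,
                           ssgseaAlpha = 0.25, panelSize = 15L,
                           qLo = 0.25, qHi = 0.75, seed = 1L) {
  cfg <- list(simulation = simulation, stages = stages,
              minCoverage = minCoverage, minOverlap = as.integer(minOverlap),
              splitHalfRepeats = as.integer(splitHalfRepeats),
              K = as.integer(K), innerK = as.integer(innerK),
              model = model, ridgeLambda = ridgeLambda, B = as.integer(B),
              nTop = as.integer(nTop), stabilityMin = stabilityMin,
              ssgseaAlpha = ssgseaAlpha, panelSize = as.integer(panelSize),
              qLo = qLo, qHi = qHi, seed = as.integer(seed))
  cfg$simulation@seed <- cfg$seed
  class(cfg) <- "fgfriPipelineConfig"
  cfg
}

configAsList <- function(cfg) {
  sim <- cfg$simulation
  simList <- lapply(slotNames(sim), function(s) slot(sim, s))
  names(simList) <- slotNames(sim)
  simList$axisGeneSigns <- as.list(sim@axisGeneSigns)
  c(list(simulation = simList), cfg[setdiff(names(cfg), "simulation")])
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline on simulated or supplied inputs
#'
#' Executes the enabled stages in order -- simulate (or read supplied
#' matrices), phenotype (coverage filter, standardization, QC weights,
#' composites, split-half), train (leakage-safe OOF fit, optional
#' permutation test), signature (fold-averaged ridge weights, reduced
#' panel), project (cohort scoring and validation statistics) -- writing
#' each artifact under `outDir` and returning a manifest that lists every
#' file with its md5 hash. Identical config + seed reproduce identical
#' hashes.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @param inputs optional list with elements `responses` (cell lines x drugs
#'   matrix), `expression` (genes x lines), `cohort` (genes x samples) to
#'   use instead of the simulate stage.
#' @return the manifest (list), invisibly written as manifest.json.
#' @examples
#' cfg <- pipelineConfig(simulationConfig(nCellLines = 50, nDrugs = 8,
#'                                        nGenes = 60, nSignatureGenes = 8,
#'                                        cohortNSamples = 30),
#'                       splitHalfRepeats = 20, K = 3, nTop = 10,
#'                       minOverlap = 10, seed = 11)
#' man <- runPipeline(cfg, tempfile("run"))
#' names(man$artifacts)
#' @export
runPipeline <- function(config, outDir, inputs = NULL) {
  stopifnot(inherits(config, "fgfriPipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  addArtifact <- function(name, path) {
    artifacts[[name]] <<- list(file = basename(path),
                               md5 = unname(tools::md5sum(path)))
  }
  fmt <- function(x) as.numeric(format(x, digits = 15))
  writeJson(configAsList(config), file.path(outDir, "config.json"))
  addArtifact("config", file.path(outDir, "config.json"))
  stages <- config$stages
  sim <- NULL; cohort <- NULL

  if ("simulate" %in% stages && is.null(inputs)) {
    sim <- simulateCellLinePanel(config$simulation)
    cohortSim <- simulateTumorCohort(config$simulation, sim$truth)
    cohort <- cohortSim$expression
    matched <- simulateMatchedPlatform(sim$truth, config$simulation)
    writeMatrix(sim$responses@values, file.path(outDir, "responses.tsv"))
    writeMatrix(sim$expression, file.path(outDir, "expression.tsv"))
    writeMatrix(cohort, file.path(outDir, "cohort.tsv"))
    utils::write.table(matched, file.path(outDir, "matched_platform.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truthList <- list(
      latentSensitivity = fmt(sim$truth@latentSensitivity),
      drugLoadings = fmt(sim$truth@drugLoadings),
      cohortLatent = fmt(cohortSim$truth@cohortLatent))
    writeJson(truthList, file.path(outDir, "ground_truth.json"))
    for (f in c("responses.tsv", "expression.tsv", "cohort.tsv",
                "matched_platform.tsv", "ground_truth.json"))
      addArtifact(sub("\\.(tsv|json)$", "", f), file.path(outDir, f))
    responses <- sim$responses
    expression <- sim$expression
  } else {
    if (is.null(inputs))
      stop("simulate stage disabled and no inputs supplied")
    responses <- new("DrugResponseMatrix", values = inputs$responses,
                     qcLog = character(0))
    expression <- inputs$expression
    cohort <- inputs$cohort
    matched <- inputs$matched
  }

  scores <- NULL; z <- NULL
  if ("phenotype" %in% stages) {
    filtered <- filterDrugsByCoverage(responses, config$minCoverage)
    z <- standardizeAndOrient(filtered)
    qc <- computeWeights(pairwiseConcordance(z, config$minOverlap))
    scores <- suppressWarnings(compositeScores(z, qc))
    sh <- splitHalfReliability(z, nRepeats = config$splitHalfRepeats,
                               seed = stageSeed(config$seed, "splithalf"))
    confound <- coverageConfoundCheck(scores)
    utils::write.table(scoreTable(scores),
                       file.path(outDir, "composite_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    phenoSummary <- list(
      coverage = as.list(fmt(qc@coverage)),
      meanConcordance = as.list(fmt(qc@meanConcordance)),
      weights = as.list(fmt(qc@weights)),
      medianSplitHalfRho = fmt(stats::median(sh@rho)),
      coverageConfound = list(rho = fmt(confound$rho), p = fmt(confound$p),
                              status = confound$status))
    writeJson(phenoSummary, file.path(outDir, "phenotype_summary.json"))
    addArtifact("composite_scores", file.path(outDir, "composite_scores.tsv"))
    addArtifact("phenotype_summary",
                file.path(outDir, "phenotype_summary.json"))
  }

  oof <- NULL
  if ("train" %in% stages && !is.null(scores)) {
    y <- scores@weightedScore
    y <- y[!is.na(y)]
    expr <- varianceFilter(expression[, names(y), drop = FALSE])
    plan <- makeFoldPlan(names(y), K = config$K,
                         seed = stageSeed(config$seed, "folds"))
    spec <- modelSpec(config$model, grid = if (config$model == "ridge")
      list(lambda = config$ridgeLambda) else NULL,
      innerK = config$innerK)
    oof <- fitPredictOOF(expr, y, plan, spec,
                         seed = stageSeed(config$seed, "train"))
    ev <- evaluateOOF(oof)
    utils::write.table(oofTable(oof), file.path(outDir, "oof.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trainSummary <- list(family = spec@family, rho = fmt(ev$rho),
                         p = fmt(ev$p), n = ev$n,
                         foldParams = lapply(oof@foldModels, function(m)
                           as.list(m$params)))
    if (config$B > 0L) {
      pt <- permutationTest(expr, y, plan, spec, B = config$B,
                            seed = stageSeed(config$seed, "perm"))
      trainSummary$permutation <- list(B = config$B, p = fmt(pt@p),
                                       rhoObs = fmt(pt@rhoObs))
    }
    writeJson(trainSummary, file.path(outDir, "train_summary.json"))
    addArtifact("oof", file.path(outDir, "oof.tsv"))
    addArtifact("train_summary", file.path(outDir, "train_summary.json"))
  }

  sig <- NULL
  if ("signature" %in% stages && !is.null(oof)) {
    if (!oof@family %in% c("ridge", "elastic_net")) {
      y <- oof@observed
      expr <- varianceFilter(expression[, names(y), drop = FALSE])
      plan <- makeFoldPlan(names(y), K = config$K,
                           seed = stageSeed(config$seed, "folds"))
      oofLin <- fitPredictOOF(expr, y, plan,
                              modelSpec("ridge",
                                        grid = list(lambda =
                                                      config$ridgeLambda),
                                        innerK = config$innerK),
                              seed = stageSeed(config$seed, "train"))
    } else oofLin <- oof
    sig <- deriveSignature(foldCoefficients(oofLin), nTop = config$nTop,
                           stabilityMin = config$stabilityMin)
    y <- oofLin@observed
    expr <- varianceFilter(expression[, names(y), drop = FALSE])
    panel <- suppressWarnings(deriveReducedPanel(
      expr, y, size = config$panelSize, K = config$K,
      seed = stageSeed(config$seed, "panel")))
    sigJson <- list(
      up = as.list(stats::setNames(fmt(sig@meanWeight[sig@upGenes]),
                                   sig@upGenes)),
      down = as.list(stats::setNames(fmt(sig@meanWeight[sig@downGenes]),
                                     sig@downGenes)),
      panel = as.list(stats::setNames(fmt(panel@weights), panel@genes)))
    writeJson(sigJson, file.path(outDir, "signature.json"))
    addArtifact("signature", file.path(outDir, "signature.json"))
    attr(sig, "panel") <- panel
  }

  if ("project" %in% stages && !is.null(sig) && !is.null(cohort)) {
    ud <- updownScore(cohort, sig)
    ss <- ssgseaScore(cohort, sig@upGenes, sig@downGenes,
                      alpha = config$ssgseaAlpha)
    rk <- rankScore(cohort, sig)
    pn <- panelScore(cohort, attr(sig, "panel"))
    scoresDf <- rbind(scoreTable(ud), scoreTable(ss), scoreTable(rk),
                      scoreTable(pn))
    scoresDf$score <- as.numeric(fmt(scoresDf$score))
    utils::write.table(scoresDf, file.path(outDir, "cohort_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    axisGenes <- names(config$simulation@axisGeneSigns)
    ax <- axisCorrelations(ud, cohort, axisGenes)
    projSummary <- list(
      axis = lapply(seq_len(nrow(ax)), function(i)
        list(gene = ax$gene[i], rho = fmt(ax$rho[i]), p = fmt(ax$p[i]),
             n = ax$n[i], status = ax$status[i])),
      methodConcordance = list(
        updown_ssgsea = fmt(scoreConcordance(ud, ss)$rho),
        updown_rank = fmt(scoreConcordance(ud, rk)$rho),
        updown_panel = fmt(scoreConcordance(ud, pn)$rho)))
    writeJson(projSummary, file.path(outDir, "projection_summary.json"))
    addArtifact("cohort_scores", file.path(outDir, "cohort_scores.tsv"))
    addArtifact("projection_summary",
                file.path(outDir, "projection_summary.json"))
  }

  manifest <- list(seed = config$seed, stages = stages,
                   artifacts = artifacts)
  writeJson(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}
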