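#' Pipeline run configuration
#'
#' Bundles every stage's parameters. Two profiles are provided:
#' `"paper"` (46 subjects per group, 10,000/5,000/5,000/5,000
#' permutations, 100 null graphs, 100 CV repeats) and `"test"` (20 per
#' group, 199/199/199/99 permutations, 20 null graphs, 10 CV repeats) for
#' fast smoke runs. The config round-trips losslessly through YAML via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param profile "paper" or "test"; sets the defaults below.
#' @param simulation a [simulationConfig()] (or NULL to read a cohort from
#'   `cohortDir`).
#' @param cohortDir directory to read/write the cohort.
#' @param outDir output directory for all artifacts.
#' @param grid a [thresholdGrid()].
#' @param seed master seed for every stage.
#' @param nNull rewired nulls per graph for sigma.
#' @param restarts Louvain restarts.
#' @param nPermGlobal,nPermNodal,nPermNbs,nPermClassifier permutation
#'   counts.
#' @param alpha significance level for flagging features.
#' @param alphaPrimary NBS primary edge threshold.
#' @param nbsTails NBS tail directions to run.
#' @param svmCost,cvFolds,cvRepeats classifier options.
#' @param lassoRepeats LASSO CV repeats.
#' @param leakageMode "leaky" (selection before CV, the reproduction
#'   default) or "nested".
#' @return A `RunConfig` (classed list).
#' @export
pipelineConfig <- function(profile = c("test", "paper"), simulation = NULL,
                           cohortDir = NULL, outDir = tempfile("wmconn-run-"),
                           grid = thresholdGrid(), seed = 1L, nNull = NULL,
                           restarts = NULL, nPermGlobal = NULL,
                           nPermNodal = NULL, nPermNbs = NULL,
                           nPermClassifier = NULL, alpha = 0.05,
                           alphaPrimary = 0.05,
                           nbsTails = c("patient>control", "control>patient"),
                           svmCost = 1, cvFolds = 5L, cvRepeats = NULL,
                           lassoRepeats = 10L,
                           leakageMode = c("leaky", "nested")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(nNull = 100L, restarts = 20L, nPermGlobal = 10000L,
         nPermNodal = 5000L, nPermNbs = 5000L, nPermClassifier = 5000L,
         cvRepeats = 100L, nPerGroup = 46L)
  else
    list(nNull = 20L, restarts = 5L, nPermGlobal = 199L, nPermNodal = 199L,
         nPermNbs = 199L, nPermClassifier = 99L, cvRepeats = 10L,
         nPerGroup = 20L)
  pick <- function(x, d) if (is.null(x)) d else x
  if (is.null(simulation) && is.null(cohortDir))
    simulation <- simulationConfig(nPerGroup = def$nPerGroup, seed = seed)
  cfg <- list(profile = profile, simulation = simulation,
              cohortDir = cohortDir, outDir = outDir,
              grid = as.numeric(grid), seed = as.integer(seed),
              nNull = pick(nNull, def$nNull),
              restarts = pick(restarts, def$restarts),
              nPermGlobal = pick(nPermGlobal, def$nPermGlobal),
              nPermNodal = pick(nPermNodal, def$nPermNodal),
              nPermNbs = pick(nPermNbs, def$nPermNbs),
              nPermClassifier = pick(nPermClassifier, def$nPermClassifier),
              alpha = alpha, alphaPrimary = alphaPrimary,
              nbsTails = nbsTails, svmCost = svmCost,
              cvFolds = as.integer(cvFolds),
              cvRepeats = pick(cvRepeats, def$cvRepeats),
              lassoRepeats = as.integer(lassoRepeats),
              leakageMode = match.arg(leakageMode))
  stopifnot(all(unlist(cfg[c("nNull", "nPermGlobal", "nPermNodal",
                             "nPermNbs", "nPermClassifier", "cvFolds",
                             "cvRepeats")]) >= 1))
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a `RunConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  raw <- unclass(cfg)
  raw$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  raw$simulation <- NULL
  args <- raw[setdiff(names(raw), c("profile", "grid"))]
  g <- raw$grid
  cfg <- do.call(pipelineConfig, c(
    list(profile = raw$profile,
         grid = thresholdGrid(g[1], g[length(g)], g[2] - g[1]),
         simulation = if (!is.null(sim)) do.call(simulationConfig, sim)),
    args))
  cfg
}

#' Select features, train the classifier and test its significance
#'
#' The reproduction ordering: restricts the table to the
#' significantly different features, runs LASSO selection, the repeated
#' cross-validated linear SVM and the label-permutation test, and returns
#' the completed [ClassifierReport-class].
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param significant character vector of candidate feature names.
#' @param svmCost,cvFolds,cvRepeats,lassoRepeats classifier options.
#' @param nPerm label permutations (0 skips the permutation test).
#' @param seed integer seed.
#' @return A [ClassifierReport-class].
#' @export
classifyFeatures <- function(ft, significant, svmCost = 1, cvFolds = 5L,
                             cvRepeats = 100L, lassoRepeats = 10L,
                             nPerm = 5000L, seed = 1L) {
  if (length(significant) < 2L)
    stop("need at least 2 candidate features for selection")
  X <- t(SummarizedExperiment::assay(ft, "auc"))[, significant, drop = FALSE]
  labels <- as.character(SummarizedExperiment::colData(ft)$group)
  sel <- lassoSelect(X, labels, repeats = lassoRepeats, folds = cvFolds,
                     seed = seed)
  rep <- svmCrossval(X[, sel$selected, drop = FALSE], labels, c = svmCost,
                     folds = cvFolds, repeats = cvRepeats, seed = seed)
  if (nPerm > 0L) {
    pt <- permutationTestClassifier(
      X[, sel$selected, drop = FALSE], labels, nPerm = nPerm, seed = seed,
      c = svmCost, folds = cvFolds,
      trueAccuracy = classifierMetrics(rep)["accuracy", "mean"])
    rep@permP <- pt$permP
    rep@permPSmoothed <- pt$permPSmoothed
    rep@nPerm <- pt$nPerm
  }
  rep
}

#' Run the whole pipeline end to end
#'
#' simulate (or load) -> feature table -> group inference -> clinical
#' correlations -> NBS (both tails by default) -> classification with
#' permutation test -> leakage audit. Every stage writes its artifact
#' under `cfg$outDir` and a manifest ties outputs to input digests and the
#' seed. Deterministic given the config.
#'
#' @param cfg a [pipelineConfig()].
#' @return A list with every stage's in-memory result and the artifact
#'   paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- thresholdGrid(cfg$grid[1], cfg$grid[length(cfg$grid)],
                        cfg$grid[2] - cfg$grid[1])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  coh <- if (!is.null(cfg$simulation)) {
    stage("simulate", {
      co <- generateCohort(cfg$simulation)
      writeCohortDir(co, file.path(cfg$outDir, "cohort"))
      co
    })
  } else stage("load-cohort", readCohortDir(cfg$cohortDir))

  ft <- stage("metrics", buildFeatureTable(coh, grid, seed = cfg$seed,
                                           nNull = cfg$nNull,
                                           restarts = cfg$restarts))
  writeFeatureTable(ft, file.path(cfg$outDir, "features.tsv"))

  cmp <- stage("compare", compareFeatures(
    ft, nPermGlobal = cfg$nPermGlobal, nPermNodal = cfg$nPermNodal,
    seed = cfg$seed, alpha = cfg$alpha))
  utils::write.table(cmp, file.path(cfg$outDir, "comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sig <- attr(cmp, "significant")

  cors <- stage("correlate", if (length(sig))
    clinicalCorrelations(ft, sig) else NULL)
  if (!is.null(cors))
    utils::write.table(cors, file.path(cfg$outDir, "clinical_correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  nbs <- stage("nbs", lapply(stats::setNames(cfg$nbsTails, cfg$nbsTails),
    function(tl) nbsTest(coh, alphaPrimary = cfg$alphaPrimary,
                         nPerm = cfg$nPermNbs, seed = cfg$seed, tail = tl)))
  for (tl in names(nbs))
    writeReport(nbs[[tl]],
                file.path(cfg$outDir, paste0("nbs_", gsub("[^a-z]", "_", tl),
                                             ".json")),
                seed = cfg$seed)

  clf <- stage("classify", if (length(sig) >= 2L)
    classifyFeatures(ft, sig, svmCost = cfg$svmCost, cvFolds = cfg$cvFolds,
                     cvRepeats = cfg$cvRepeats,
                     lassoRepeats = cfg$lassoRepeats,
                     nPerm = cfg$nPermClassifier, seed = cfg$seed)
    else NULL)
  if (!is.null(clf)) {
    writeReport(clf, file.path(cfg$outDir, "classifier.json"), seed = cfg$seed)
    utils::write.table(
      data.frame(feature = names(featureWeights(clf)),
                 weight = featureWeights(clf)),
      file.path(cfg$outDir, "feature_weights.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  audit <- stage("leakage-audit", if (length(sig) >= 2L) {
    X <- t(SummarizedExperiment::assay(ft, "auc"))
    leakageAudit(X, SummarizedExperiment::colData(ft)$group,
                 nRepeats = 5L, seed = cfg$seed, alpha = cfg$alpha,
                 c = cfg$svmCost, folds = cfg$cvFolds)
  } else NULL)

  manifest <- list(
    schema = "wmconn-manifest-1", seed = cfg$seed, profile = cfg$profile,
    leakageMode = cfg$leakageMode,
    rVersion = as.character(getRversion()),
    artifacts = as.list(tools::md5sum(list.files(cfg$outDir,
                                                 pattern = "\\.(tsv|json)$",
                                                 full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(cohort = coh, features = ft, comparison = cmp, significant = sig,
       clinical = cors, nbs = nbs, classifier = clf, leakage = audit,
       outDir = cfg$outDir)
}
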