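#' @import methods
#' @importFrom stats sd quantile rnorm runif rlnorm rbinom cor pt setNames
#' @importFrom utils read.table write.table head modifyList
NULL

#' ConnectivityMatrix: one subject's weighted structural connectome
#'
#' Holds a symmetric nonnegative node-by-node matrix of tractography
#' connection probabilities (unitless, in \[0,1\]) together with the subject
#' identifier and the ordered node labels. The diagonal is zero and the
#' matrix is validated as symmetric to within 1e-9.
#'
#' @slot subjectId character(1) subject identifier.
#' @slot weights numeric N x N matrix of connection probabilities.
#' @slot nodeIds character(N) ordered node labels (row/column order).
#'
#' @seealso [connectivityMatrix()], [readConnectivityMatrix()]
#' @export
setClass("ConnectivityMatrix",
  representation(subjectId = "character", weights = "matrix",
                 nodeIds = "character"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msgs <- c(msgs, "subjectId must be a single non-NA string")
  if (!is.numeric(w) || nrow(w) != ncol(w))
    return("weights must be a square numeric matrix")
  n <- nrow(w)
  if (n < 3L) msgs <- c(msgs, "matrix must have at least 3 nodes")
  if (length(object@nodeIds) != n)
    msgs <- c(msgs, "nodeIds length must match matrix dimension")
  if (anyDuplicated(object@nodeIds))
    msgs <- c(msgs, "nodeIds must be unique")
  if (anyNA(w)) {
    bad <- which(is.na(w), arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf("NaN/NA entry at (%d,%d)", bad[1L], bad[2L]))
  } else {
    if (any(w < 0)) {
      bad <- which(w < 0, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf("negative entry at (%d,%d)", bad[1L], bad[2L]))
    }
    asym <- abs(w - t(w))
    if (max(asym) > 1e-9) {
      bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf(
        "asymmetry beyond tolerance at cells (%d,%d)/(%d,%d)",
        bad[1L], bad[2L], bad[2L], bad[1L]))
    }
    if (any(diag(w) != 0))
      msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cohort: subject records, matrices and atlas bundled together
#'
#' @slot records data.frame of subject records (one row per subject; columns
#'   `subject_id`, `group`, covariates and clinical scores).
#' @slot matrices named list of [ConnectivityMatrix-class] objects keyed by
#'   subject id.
#' @slot atlas data.frame node table (`node_id`, `region_name`, `hemisphere`,
#'   `subnetwork`); may have zero rows if no atlas is attached.
#'
#' @seealso [generateCohort()], [readCohortDir()]
#' @export
setClass("Cohort",
  representation(records = "data.frame", matrices = "list",
                 atlas = "data.frame"))

setValidity("Cohort", function(object) {
  msgs <- character()
  ids <- object@records$subject_id
  if (is.null(ids)) return("records must contain a subject_id column")
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate subject_id in records")
  if (!setequal(names(object@matrices), ids))
    msgs <- c(msgs, "matrices must be keyed by exactly the record subject ids")
  dims <- vapply(object@matrices, function(m) nrow(m@weights), integer(1))
  if (length(unique(dims)) > 1L)
    msgs <- c(msgs, "all matrices must share one dimension")
  nodeSets <- unique(lapply(object@matrices, function(m) m@nodeIds))
  if (length(nodeSets) > 1L)
    msgs <- c(msgs, "all matrices must share one node ordering")
  if (nrow(object@atlas) > 0L && length(dims) > 0L &&
      nrow(object@atlas) != dims[[1L]])
    msgs <- c(msgs, "atlas row count must equal the matrix dimension")
  if (!all(object@records$group %in% c("patient", "control")))
    msgs <- c(msgs, "group must be 'patient' or 'control'")
  if (length(msgs)) msgs else TRUE
})

#' NBSResult: network-based statistic inference result
#'
#' @slot components list of data.frames, one per observed suprathreshold
#'   component, with columns `from`, `to`, `t`, `p` (node labels, edge
#'   statistic, one-tailed p).
#' @slot sizes integer vector of component sizes (number of links).
#' @slot fweP numeric family-wise-error-corrected p per component.
#' @slot nullMaxSizes integer vector, permutation null distribution of the
#'   maximum component size.
#' @slot params list of parameters used (alphaPrimary, nPerm, tail, seed).
#' @export
setClass("NBSResult",
  representation(components = "list", sizes = "integer", fweP = "numeric",
                 nullMaxSizes = "integer", params = "list"))

setValidity("NBSResult", function(object) {
  msgs <- character()
  if (length(object@sizes) != length(object@components) ||
      length(object@fweP) != length(object@components))
    msgs <- c(msgs, "components, sizes and fweP must have equal length")
  if (length(object@sizes) && any(object@sizes < 1L))
    msgs <- c(msgs, "component sizes must be >= 1")
  if (length(object@fweP) &&
      (any(object@fweP <= 0) || any(object@fweP > 1)))
    msgs <- c(msgs, "fweP must lie in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' ClassifierReport: cross-validated linear-SVM performance
#'
#' Performance rates are on the percent scale, each reported as mean and sd
#' over all fold evaluations (folds x repeats).
#'
#' @slot metrics data.frame with rows accuracy, sensitivity, specificity,
#'   kappa and columns mean, sd (percent scale).
#' @slot selectedFeatures character vector of feature names used.
#' @slot featureWeights named numeric, mean absolute linear-SVM primal weight
#'   per selected feature.
#' @slot params list: c (SVM cost), folds, repeats, seed, nFoldEvaluations.
#' @slot permP numeric, label-permutation p (raw count/nPerm); NA until
#'   [permutationTestClassifier()] has been run.
#' @slot permPSmoothed numeric, (1+count)/(1+nPerm) companion.
#' @slot nPerm integer, permutations used for permP (0 if not run).
#' @export
setClass("ClassifierReport",
  representation(metrics = "data.frame", selectedFeatures = "character",
                 featureWeights = "numeric", params = "list",
                 permP = "numeric", permPSmoothed = "numeric",
                 nPerm = "integer"))

setValidity("ClassifierReport", function(object) {
  m <- object@metrics
  msgs <- character()
  need <- c("accuracy", "sensitivity", "specificity", "kappa")
  if (!all(need %in% rownames(m)))
    msgs <- c(msgs, "metrics must contain accuracy/sensitivity/specificity/kappa")
  else {
    rates <- m[c("accuracy", "sensitivity", "specificity"), "mean"]
    if (any(rates < 0 | rates > 100))
      msgs <- c(msgs, "rates must lie in [0,100] percent")
    if (m["kappa", "mean"] < -100 || m["kappa", "mean"] > 100)
      msgs <- c(msgs, "kappa must lie in [-100,100] percent")
  }
  if (length(object@featureWeights) && any(object@featureWeights < 0))
    msgs <- c(msgs, "feature weights must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights
  cat(sprintf("ConnectivityMatrix '%s': %d nodes, %d nonzero edges, max weight %.4g\n",
              object@subjectId, nrow(w), sum(w[upper.tri(w)] > 0), max(w)))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@records$group)
  cat(sprintf("Cohort: %d subjects (%s), %d nodes%s\n",
              nrow(object@records),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              if (length(object@matrices)) nrow(object@matrices[[1L]]@weights) else 0L,
              if (nrow(object@atlas)) ", atlas attached" else ""))
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf("NBSResult (tail %s, primary alpha %.3g, %d permutations)\n",
              object@params$tail, object@params$alphaPrimary,
              object@params$nPerm))
  if (!length(object@sizes)) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(object@sizes))
      cat(sprintf("  component %d: %d links, FWE p = %.4g\n",
                  k, object@sizes[k], object@fweP[k]))
  }
})

setMethod("show", "ClassifierReport", function(object) {
  m <- object@metrics
  cat("ClassifierReport (linear SVM, C =", object@params$c, ")\n")
  for (r in rownames(m))
    cat(sprintf("  %-12s %6.2f%% +/- %.2f%%\n", r, m[r, "mean"], m[r, "sd"]))
  cat(sprintf("  %d features, %d fold evaluations",
              length(object@selectedFeatures), object@params$nFoldEvaluations))
  if (object@nPerm > 0L)
    cat(sprintf(", permutation p = %.4g (%d perms)", object@permP, object@nPerm))
  cat("\n")
})
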