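#' Area under a metric curve across the threshold grid
#'
#' Trapezoidal integral of one topological attribute over the threshold
#' axis, collapsing the per-threshold curve into one scalar per subject so
#' no single arbitrary threshold drives the analysis.
#'
#' @param values numeric vector, one finite value per grid point.
#' @param grid a [thresholdGrid()].
#' @return The trapezoidal integral (units: metric x threshold).
#' @export
#' @examples
#' aucOverGrid(rep(2, 10), thresholdGrid())  # 2 * 0.009 = 0.018
aucOverGrid <- function(values, grid) {
  stopifnot(inherits(grid, "ThresholdGrid"))
  taus <- as.numeric(grid)
  if (length(values) != length(taus))
    stop(sprintf("length mismatch: %d values for %d grid points",
                 length(values), length(taus)))
  bad <- !is.finite(values)
  if (any(bad))
    stop(sprintf("non-finite metric value at threshold(s) %s",
                 paste(signif(taus[bad], 4), collapse = ", ")))
  pracma::trapz(taus, values)
}

#' Build the subject-by-feature AUC table
#'
#' For every subject and grid threshold, computes all topological
#' attributes and integrates each across the grid, yielding `4 + 2N`
#' features: global `cp`, `lp`, `q`, `sigma` plus per-node `enod_<node>`
#' and `hub_<node>`. Returned as a `SummarizedExperiment` with assay
#' `"auc"` (features x subjects), feature metadata in `rowData` (attribute
#' and node), subject records in `colData`, and the raw per-threshold
#' metric curves cached in `metadata()$curves` for audit.
#'
#' @param coh a [Cohort-class].
#' @param grid a [thresholdGrid()].
#' @param seed integer master seed; per-subject streams are derived from
#'   subject ids, so the result is independent of subject order.
#' @param nNull null graphs per threshold for sigma (default 100).
#' @param restarts Louvain restarts (default 20).
#' @return A `SummarizedExperiment` feature table.
#' @export
buildFeatureTable <- function(coh, grid = thresholdGrid(), seed = 1L,
                              nNull = 100L, restarts = 20L) {
  recs <- subjectRecords(coh)
  nodes <- nodeIds(coh)
  nN <- length(nodes)
  featNames <- c("cp", "lp", "q", "sigma",
                 paste0("enod_", nodes), paste0("hub_", nodes))
  taus <- as.numeric(grid)
  auc <- matrix(NA_real_, nrow = length(featNames), ncol = nrow(recs),
                dimnames = list(featNames, recs$subject_id))
  curves <- list()
  for (sid in recs$subject_id) {
    cm <- connMatrices(coh)[[sid]]
    subSeed <- deriveSeed(seed, paste0(sid, ":metrics"))
    curve <- matrix(NA_real_, nrow = length(featNames), ncol = length(taus),
                    dimnames = list(featNames, signif(taus, 6)))
    for (ti in seq_along(taus)) {
      g <- thresholdGraph(cm, taus[ti])
      m <- tryCatch(
        computeAllMetrics(g, seed = deriveSeed(subSeed, paste0("tau:", ti)),
                          nNull = nNull, restarts = restarts),
        error = function(e) stop(sprintf(
          "metric computation failed for subject '%s' at threshold %g: %s",
          sid, taus[ti], conditionMessage(e)), call. = FALSE))
      curve["cp", ti] <- m$global$cp
      curve["lp", ti] <- m$global$lp
      curve["q", ti] <- m$global$q
      curve["sigma", ti] <- m$global$sigma
      curve[paste0("enod_", m$nodal$node), ti] <- m$nodal$enod
      curve[paste0("hub_", m$nodal$node), ti] <- m$nodal$hubness
    }
    auc[, sid] <- apply(curve, 1L, aucOverGrid, grid = grid)
    curves[[sid]] <- curve
  }
  rowDat <- S4Vectors::DataFrame(
    attribute = c("cp", "lp", "q", "sigma",
                  rep("enod", nN), rep("hubness", nN)),
    node = c(rep(NA_character_, 4L), nodes, nodes),
    scope = c(rep("global", 4L), rep("nodal", 2L * nN)),
    row.names = featNames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(auc = auc), rowData = rowDat,
    colData = S4Vectors::DataFrame(recs, row.names = recs$subject_id))
  S4Vectors::metadata(se) <- list(curves = curves, grid = taus, seed = seed,
                                  nNull = nNull)
  se
}

#' Write a feature table as TSV plus a JSON sidecar of column metadata
#'
#' @param ft a feature-table `SummarizedExperiment` from
#'   [buildFeatureTable()].
#' @param path TSV output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  m <- t(SummarizedExperiment::assay(ft, "auc"))
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- as.data.frame(SummarizedExperiment::rowData(ft))
  jsonlite::write_json(
    list(schema = "wmconn-features-1",
         grid = S4Vectors::metadata(ft)$grid,
         seed = S4Vectors::metadata(ft)$seed,
         features = cbind(name = rownames(meta), meta)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
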