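#' Construct a validated ConnectivityMatrix
#'
#' Applies the loader contract: near-symmetric input (max |A - t(A)| <=
#' 1e-9) is symmetrized by averaging, a nonzero diagonal is forced to zero
#' with a warning, and any violation beyond tolerance is rejected naming the
#' offending cells.
#'
#' @param weights square numeric matrix of nonnegative connection
#'   probabilities.
#' @param nodeIds optional character vector of node labels; defaults to
#'   `"n1" ... "nN"`.
#' @param subjectId subject identifier string.
#' @return A [ConnectivityMatrix-class] object.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5
#' connectivityMatrix(w, subjectId = "toy")
connectivityMatrix <- function(weights, nodeIds = NULL, subjectId = "subject") {
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights))
    stop("weights must be a square numeric matrix")
  if (anyNA(weights)) {
    bad <- which(is.na(weights), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN entry at (%d,%d)", bad[1L], bad[2L]))
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at (%d,%d)", bad[1L], bad[2L]))
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > 1e-9) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    if (bad[1L] > bad[2L]) bad <- rev(bad)     # report the upper cell first
    stop(sprintf("asymmetry beyond tolerance at cells (%d,%d)/(%d,%d): %g vs %g",
                 bad[1L], bad[2L], bad[2L], bad[1L],
                 weights[bad[1L], bad[2L]], weights[bad[2L], bad[1L]]))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning(sprintf("nonzero diagonal in subject '%s' forced to zero", subjectId))
    diag(weights) <- 0
  }
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(nrow(weights)))
  dimnames(weights) <- list(nodeIds, nodeIds)
  new("ConnectivityMatrix", subjectId = as.character(subjectId),
      weights = weights, nodeIds = as.character(nodeIds))
}

#' Read a connection-probability matrix from dense CSV
#'
#' The dialect is fixed: comma separator, '.' decimal, an optional single
#' header row of node ids; row order defines node order. N rows by N numeric
#' columns.
#'
#' @param path path to the CSV file.
#' @param nodeIds optional node labels overriding any header.
#' @param subjectId subject identifier; defaults to the file name without
#'   extension.
#' @return A [ConnectivityMatrix-class].
#' @export
readConnectivityMatrix <- function(path, nodeIds = NULL, subjectId = NULL) {
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^[-0-9.eE+, \t]*$", first)
  df <- utils::read.csv(path, header = hasHeader,
                        colClasses = "numeric", check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("non-square input: %d rows x %d columns in '%s'",
                 nrow(m), ncol(m), path))
  if (is.null(nodeIds) && hasHeader) nodeIds <- colnames(df)
  connectivityMatrix(m, nodeIds = nodeIds, subjectId = subjectId)
}

#' Write a ConnectivityMatrix as dense CSV (header row of node ids)
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeConnectivityMatrix <- function(cm, path) {
  utils::write.table(weightsMatrix(cm), path, sep = ",", row.names = FALSE,
                     col.names = nodeIds(cm), quote = FALSE)
  invisible(path)
}

#' Read the subject metadata table (TSV)
#'
#' Required columns: `subject_id`, `group` (patient/control), `age`,
#' `education`, `ftnd`. Clinical columns (`bprs_total`, the five BPRS factor
#' scores, `hama`) must be present and complete for patients; controls may
#' leave them empty.
#'
#' @param path path to the TSV file.
#' @return data.frame of typed subject records.
#' @export
readSubjectTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validateSubjectTable(df)
}

#' Validate a subject-record data.frame
#'
#' @param df data.frame of candidate subject records.
#' @return The validated data.frame (group as character).
#' @export
validateSubjectTable <- function(df) {
  cols <- .recordColumns()
  need <- c("subject_id", "group", cols$covariates)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subject table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (cc in cols$covariates) {
    if (anyNA(df[[cc]]) || !all(is.finite(df[[cc]])))
      stop(sprintf("missing or non-finite covariate '%s'", cc))
  }
  for (cc in intersect(cols$clinical, names(df))) {
    badRows <- df$group == "patient" & is.na(df[[cc]])
    if (any(badRows))
      stop(sprintf("missing clinical score '%s' for patient(s): %s", cc,
                   paste(df$subject_id[badRows], collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read the atlas node table (TSV)
#'
#' Columns: `node_id`, `region_name`, `hemisphere` (L/R), `subnetwork`.
#'
#' @param path path to the TSV file.
#' @return data.frame atlas table with unique node ids.
#' @export
readAtlasTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("node_id", "region_name", "hemisphere", "subnetwork")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$node_id))
    stop("duplicate node_id in atlas table")
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  df
}

#' Assemble a Cohort from records, matrices and an optional atlas
#'
#' @param records data.frame of subject records.
#' @param matrices named list of [ConnectivityMatrix-class] keyed by subject
#'   id.
#' @param atlas optional atlas data.frame.
#' @return A validated [Cohort-class].
#' @export
cohort <- function(records, matrices, atlas = NULL) {
  if (is.null(atlas))
    atlas <- data.frame(node_id = character(), region_name = character(),
                        hemisphere = character(), subnetwork = character())
  new("Cohort", records = validateSubjectTable(records),
      matrices = matrices, atlas = atlas)
}

#' Write a cohort to a directory (matrices as CSV, tables as TSV)
#'
#' Layout: `subjects.tsv`, `atlas.tsv`, and `matrices/<subject_id>.csv`.
#'
#' @param coh a [Cohort-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohortDir <- function(coh, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(subjectRecords(coh), file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(atlasTable(coh)))
    utils::write.table(atlasTable(coh), file.path(dir, "atlas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (cm in connMatrices(coh))
    writeConnectivityMatrix(cm, file.path(dir, "matrices",
                                          paste0(subjectId(cm), ".csv")))
  invisible(dir)
}

#' Read a cohort directory written by [writeCohortDir()]
#'
#' @param dir directory containing `subjects.tsv`, optional `atlas.tsv` and
#'   `matrices/<subject_id>.csv`.
#' @return A validated [Cohort-class].
#' @export
readCohortDir <- function(dir) {
  records <- readSubjectTable(file.path(dir, "subjects.tsv"))
  atlas <- NULL
  if (file.exists(file.path(dir, "atlas.tsv")))
    atlas <- readAtlasTable(file.path(dir, "atlas.tsv"))
  mats <- list()
  for (sid in records$subject_id) {
    p <- file.path(dir, "matrices", paste0(sid, ".csv"))
    if (!file.exists(p)) stop(sprintf("missing matrix file for subject '%s'", sid))
    mats[[sid]] <- readConnectivityMatrix(p, subjectId = sid)
  }
  cohort(records, mats, atlas)
}

#' Write an analysis result as a JSON report
#'
#' Reports carry a schema version, the seed, optional input digests and all
#' numbers at full precision; [readReport()] restores the payload.
#'
#' @param result a list, data.frame, [NBSResult-class] or
#'   [ClassifierReport-class].
#' @param path output file path.
#' @param seed the seed that produced `result` (recorded in the report).
#' @param inputs optional character vector of input file paths to digest
#'   (md5).
#' @param timestamp logical; include a timestamp field (set `FALSE` for
#'   byte-reproducible output).
#' @return `path`, invisibly.
#' @export
writeReport <- function(result, path, seed = NA_integer_, inputs = NULL,
                        timestamp = TRUE) {
  payload <- .serializeResult(result)
  doc <- list(schema = "wmconn-report-1", type = payload$type,
              seed = seed, payload = payload$value)
  if (!is.null(inputs))
    doc$input_digests <- as.list(tools::md5sum(inputs))
  if (timestamp) doc$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [writeReport()]
#'
#' @param path report path.
#' @return A list with `type`, `seed` and the deserialized `result` (S4
#'   results are reconstructed).
#' @export
readReport <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "wmconn-report-1"))
    stop("not a wmconn report: ", path)
  list(type = doc$type, seed = doc$seed,
       result = .deserializeResult(doc$type, doc$payload),
       timestamp = doc$timestamp)
}

.serializeResult <- function(result) {
  if (is(result, "ClassifierReport")) {
    list(type = "ClassifierReport", value = list(
      metrics = cbind(metric = rownames(result@metrics), result@metrics),
      selectedFeatures = result@selectedFeatures,
      featureWeights = as.list(result@featureWeights),
      params = result@params, permP = result@permP,
      permPSmoothed = result@permPSmoothed, nPerm = result@nPerm))
  } else if (is(result, "NBSResult")) {
    list(type = "NBSResult", value = list(
      components = result@components, sizes = result@sizes,
      fweP = result@fweP, nullMaxSizes = result@nullMaxSizes,
      params = result@params))
  } else if (is.data.frame(result)) {
    list(type = "data.frame", value = result)
  } else if (is.list(result)) {
    list(type = "list", value = result)
  } else stop("unserializable result of class ", class(result)[1L])
}

.deserializeResult <- function(type, payload) {
  if (identical(type, "ClassifierReport")) {
    m <- payload$metrics
    rownames(m) <- m$metric
    m$metric <- NULL
    new("ClassifierReport", metrics = m,
        selectedFeatures = as.character(payload$selectedFeatures),
        featureWeights = unlist(payload$featureWeights),
        params = payload$params,
        permP = if (is.null(payload$permP)) NA_real_ else
          as.numeric(payload$permP),
        permPSmoothed = if (is.null(payload$permPSmoothed)) NA_real_ else
          as.numeric(payload$permPSmoothed),
        nPerm = as.integer(payload$nPerm))
  } else if (identical(type, "NBSResult")) {
    comps <- payload$components
    if (is.data.frame(comps)) comps <- list(comps)
    new("NBSResult", components = comps,
        sizes = as.integer(payload$sizes), fweP = as.numeric(payload$fweP),
        nullMaxSizes = as.integer(payload$nullMaxSizes),
        params = payload$params)
  } else payload
}
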