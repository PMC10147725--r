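#' Accessors for wmconn S4 objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a wmconn S4 object.
#' @return The corresponding component: `subjectId()` a string,
#'   `weightsMatrix()` the numeric matrix, `nodeIds()` node labels,
#'   `subjectRecords()` / `atlasTable()` data.frames, `connMatrices()` the
#'   named list of [ConnectivityMatrix-class] objects, `nbsComponents()` the
#'   component edge lists, `fweP()` corrected p-values,
#'   `classifierMetrics()` the percent-scale performance table,
#'   `selectedFeatures()` / `featureWeights()` the classifier's feature set.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("subjectRecords", function(x) standardGeneric("subjectRecords"))
#' @rdname accessors
#' @export
setGeneric("connMatrices", function(x) standardGeneric("connMatrices"))
#' @rdname accessors
#' @export
setGeneric("atlasTable", function(x) standardGeneric("atlasTable"))
#' @rdname accessors
#' @export
setGeneric("nbsComponents", function(x) standardGeneric("nbsComponents"))
#' @rdname accessors
#' @export
setGeneric("fweP", function(x) standardGeneric("fweP"))
#' @rdname accessors
#' @export
setGeneric("classifierMetrics", function(x) standardGeneric("classifierMetrics"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname accessors
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)
#' @rdname accessors
setMethod("weightsMatrix", "ConnectivityMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("nodeIds", "ConnectivityMatrix", function(x) x@nodeIds)
#' @rdname accessors
setMethod("subjectRecords", "Cohort", function(x) x@records)
#' @rdname accessors
setMethod("connMatrices", "Cohort", function(x) x@matrices)
#' @rdname accessors
setMethod("atlasTable", "Cohort", function(x) x@atlas)
#' @rdname accessors
setMethod("nodeIds", "Cohort", function(x) {
  if (!length(x@matrices)) character() else x@matrices[[1L]]@nodeIds
})
#' @rdname accessors
setMethod("nbsComponents", "NBSResult", function(x) x@components)
#' @rdname accessors
setMethod("fweP", "NBSResult", function(x) x@fweP)
#' @rdname accessors
setMethod("classifierMetrics", "ClassifierReport", function(x) x@metrics)
#' @rdname accessors
setMethod("selectedFeatures", "ClassifierReport", function(x) x@selectedFeatures)
#' @rdname accessors
setMethod("featureWeights", "ClassifierReport", function(x) x@featureWeights)
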