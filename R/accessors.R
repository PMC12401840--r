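#' @rdname accessors
#' @name accessors
#' @title Accessors for BrainGraph and BrainCohort
#' @description Slot accessors for the core data objects. `nodeFeatures()`,
#'   `anatAdjacency()`, `damageMatrix()` and `clinicalVector()` read one
#'   subject; `subjectLabels()` and `regionNames()` summarize a cohort.
#' @param x a [BrainGraph-class] or [BrainCohort-class] object.
NULL

#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "BrainGraph", function(x) x@nodeFeatures)

#' @rdname accessors
#' @export
setGeneric("anatAdjacency", function(x) standardGeneric("anatAdjacency"))
#' @rdname accessors
#' @export
setMethod("anatAdjacency", "BrainGraph", function(x) x@anatAdj)

#' @rdname accessors
#' @export
setGeneric("damageMatrix", function(x) standardGeneric("damageMatrix"))
#' @rdname accessors
#' @export
setMethod("damageMatrix", "BrainGraph", function(x) x@damage)

#' @rdname accessors
#' @export
setGeneric("clinicalVector", function(x) standardGeneric("clinicalVector"))
#' @rdname accessors
#' @export
setMethod("clinicalVector", "BrainGraph", function(x) x@clinical)

#' @rdname accessors
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @rdname accessors
#' @export
setMethod("subjectLabels", "BrainCohort", function(x) {
  vapply(x@graphs, function(g) g@label, integer(1))
})

#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setMethod("regionNames", "BrainCohort", function(x) x@regionNames)
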