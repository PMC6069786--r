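#' Accessors for GliomaCohort objects
#'
#' \code{clinicalData()} returns the clinical table (colData) as a
#' data.frame; \code{methylation()} the methylation
#' \code{SummarizedExperiment} (or \code{NULL}); \code{cohortTruth()} the
#' \linkS4class{SyntheticTruth} for simulated cohorts (or \code{NULL});
#' \code{exprsMatrix()} the expression assay as a base matrix.
#'
#' @param x A \linkS4class{GliomaCohort}.
#' @return See each accessor's description.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname cohort-accessors
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname cohort-accessors
setMethod("clinicalData", "GliomaCohort", function(x) {
  as.data.frame(colData(x))
})

#' @rdname cohort-accessors
setMethod("methylation", "GliomaCohort", function(x) x@methylation)

#' @rdname cohort-accessors
setMethod("cohortTruth", "GliomaCohort", function(x) metadata(x)$truth)

#' @rdname cohort-accessors
setMethod("exprsMatrix", "GliomaCohort", function(x) {
  as.matrix(assay(x, "exprs"))
})
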