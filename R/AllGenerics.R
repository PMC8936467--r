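#' @rdname ProgCohort
#' @export
setGeneric("exprs", function(object, ...) standardGeneric("exprs"))

#' @rdname ProgCohort
#' @export
setGeneric("aberrations", function(object, ...) standardGeneric("aberrations"))

#' @rdname ProgCohort
#' @export
setGeneric("aberrations<-",
    function(object, value) standardGeneric("aberrations<-"))

#' @rdname ProgCohort
#' @export
setGeneric("clinicalData", function(object, ...) standardGeneric("clinicalData"))

#' @rdname ProgCohort
#' @export
setGeneric("survivalData", function(object, ...) standardGeneric("survivalData"))

#' @rdname ProgCohort
#' @export
setGeneric("groundTruth", function(object, ...) standardGeneric("groundTruth"))

#' @rdname SignatureWeightSet
#' @export
setGeneric("eventLabel", function(object) standardGeneric("eventLabel"))

#' @rdname SignatureWeightSet
#' @export
setGeneric("weightPlus", function(object) standardGeneric("weightPlus"))

#' @rdname SignatureWeightSet
#' @export
setGeneric("weightMinus", function(object) standardGeneric("weightMinus"))

#' @rdname BaseScoreResult
#' @export
setGeneric("baseNull", function(object) standardGeneric("baseNull"))
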