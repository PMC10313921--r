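#' @rdname DoseResponseCurve
#' @param object,x an object.
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @rdname DoseResponseCurve
#' @export
setGeneric("respValues", function(object) standardGeneric("respValues"))

#' @rdname DoseResponseCurve
#' @export
setGeneric("curveKind", function(object) standardGeneric("curveKind"))

#' @rdname DoseResponseCurve
#' @export
setGeneric("doseUnit", function(object) standardGeneric("doseUnit"))

#' @rdname DoseResponseCurve
#' @export
setGeneric("interpolationAxis", function(object) standardGeneric("interpolationAxis"))

#' @rdname killFraction
#' @export
setGeneric("killFraction", function(object) standardGeneric("killFraction"))

#' @rdname detectShape
#' @export
setGeneric("detectShape", function(object, ...) standardGeneric("detectShape"))

#' @rdname TherapeuticWindows
#' @export
setGeneric("windowValues", function(object) standardGeneric("windowValues"))

#' @rdname TherapeuticWindows
#' @export
setGeneric("nrFlags", function(object) standardGeneric("nrFlags"))

#' @rdname WeightVector
#' @export
setGeneric("weightValues", function(object) standardGeneric("weightValues"))

#' @rdname DssResult
#' @export
setGeneric("dssScore", function(object) standardGeneric("dssScore"))

#' @rdname DssMatrix
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
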