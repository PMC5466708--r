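#' @rdname DetectionMatrix-accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname DetectionMatrix-accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname DetectionMatrix-accessors
#' @export
setGeneric("experimentIds", function(x) standardGeneric("experimentIds"))

#' @rdname DetectionMatrix-accessors
#' @export
setGeneric("unitLevel", function(x) standardGeneric("unitLevel"))

#' @rdname SaturationCurve-accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname SaturationCurve-accessors
#' @export
setGeneric("orderingLabel", function(x) standardGeneric("orderingLabel"))

#' @rdname AbundanceEstimate-accessors
#' @export
setGeneric("nHat", function(x) standardGeneric("nHat"))

#' @rdname AbundanceEstimate-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
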