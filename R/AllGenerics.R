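#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @export
setGeneric("getFeature", function(x, featureId) standardGeneric("getFeature"))

#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @export
setGeneric("opLog", function(x) standardGeneric("opLog"))

#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
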