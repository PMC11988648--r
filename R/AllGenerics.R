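#' @rdname absorbance
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname scanInfo
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' @rdname nScans
#' @export
setGeneric("nScans", function(x) standardGeneric("nScans"))

#' @rdname nWavelengths
#' @export
setGeneric("nWavelengths", function(x) standardGeneric("nWavelengths"))

#' @rdname explainedVariance
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
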