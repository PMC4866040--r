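#' @include varpsim-package.R
NULL

#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))

#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @export
setGeneric("meshResolution", function(x) standardGeneric("meshResolution"))

#' @export
setGeneric("meshSurfaces", function(x) standardGeneric("meshSurfaces"))

#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @export
setGeneric("labelFractions", function(x) standardGeneric("labelFractions"))

#' @export
setGeneric("fiberDirections", function(x) standardGeneric("fiberDirections"))

#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))

#' @export
setGeneric("vmFrames", function(x) standardGeneric("vmFrames"))

#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @export
setGeneric("siteOutcomes", function(x) standardGeneric("siteOutcomes"))

#' @export
setGeneric("overallCall", function(x) standardGeneric("overallCall"))
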