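#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))

#' @export
setGeneric("omicsNames", function(x) standardGeneric("omicsNames"))

#' @export
setGeneric("omicsLayer", function(x, name) standardGeneric("omicsLayer"))

#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setGeneric("oobVotes", function(x) standardGeneric("oobVotes"))

#' @export
setGeneric("oobCoverage", function(x) standardGeneric("oobCoverage"))

#' @export
setGeneric("tunedCutoff", function(x) standardGeneric("tunedCutoff"))

#' @export
setGeneric("syntheticNames", function(x) standardGeneric("syntheticNames"))
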