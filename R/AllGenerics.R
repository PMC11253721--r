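#' @include AllGenerics.R
NULL

#' @export
setGeneric("abundances", function(object, ...) standardGeneric("abundances"))

#' @export
setGeneric("peaks", function(object, ...) standardGeneric("peaks"))

#' @export
setGeneric("candidateInfo", function(object, ...) standardGeneric("candidateInfo"))

#' @export
setGeneric("candidateIds", function(object, ...) standardGeneric("candidateIds"))

#' @export
setGeneric("nCandidates", function(object, ...) standardGeneric("nCandidates"))

#' @export
setGeneric("nEnvelopes", function(object, ...) standardGeneric("nEnvelopes"))

#' @export
setGeneric("atomCounts", function(object, ...) standardGeneric("atomCounts"))

#' @export
setGeneric("exchangeableH", function(object, ...) standardGeneric("exchangeableH"))

#' @export
setGeneric("isFitted", function(object, ...) standardGeneric("isFitted"))

#' @export
setGeneric("binEdges", function(object, ...) standardGeneric("binEdges"))
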