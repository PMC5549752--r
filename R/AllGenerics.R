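#' @include AllClasses.R
NULL

#' OTU count matrix
#'
#' @param x an object with OTU counts.
#' @rdname otuCounts
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname taxonomy
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' Domain of an OTU table
#'
#' @param x an object with a domain.
#' @rdname otuDomain
#' @export
setGeneric("otuDomain", function(x) standardGeneric("otuDomain"))

#' @rdname sampleFractions
#' @export
setGeneric("sampleFractions", function(x) standardGeneric("sampleFractions"))

#' @rdname ledgerTable
#' @export
setGeneric("ledgerTable", function(x) standardGeneric("ledgerTable"))
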