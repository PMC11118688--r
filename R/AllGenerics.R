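#' @rdname probeGenes
#' @export
setGeneric("probeGenes", function(x) standardGeneric("probeGenes"))

#' @rdname isNegativeProbe
#' @export
setGeneric("isNegativeProbe", function(x) standardGeneric("isNegativeProbe"))

#' @rdname segmentData
#' @export
setGeneric("segmentData", function(x) standardGeneric("segmentData"))

#' @rdname loq
#' @export
setGeneric("loq", function(x) standardGeneric("loq"))

#' @rdname loq
#' @export
setGeneric("loq<-", function(x, value) standardGeneric("loq<-"))

#' @rdname isNormalized
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname sigName
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))

#' @rdname sigGenes
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))
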