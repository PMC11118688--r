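#' Probe-to-gene map
#'
#' @param x A \linkS4class{ProbeCountSet}.
#' @return Named character vector, probe id -> gene symbol.
#' @export
setMethod("probeGenes", "ProbeCountSet", function(x) {
  setNames(rowData(x)$gene, rownames(x))
})

#' Negative-control probe flags
#'
#' @param x A \linkS4class{ProbeCountSet}.
#' @return Named logical vector, probe id -> negative-control flag.
#' @export
setMethod("isNegativeProbe", "ProbeCountSet", function(x) {
  setNames(rowData(x)$negative, rownames(x))
})

#' Segment annotation table
#'
#' @param x A \linkS4class{ProbeCountSet} or \linkS4class{GeneExpressionSet}.
#' @return \code{data.frame} of per-segment annotation, rownames = segment ids.
#' @export
setMethod("segmentData", "SummarizedExperiment", function(x) {
  as.data.frame(colData(x))
})

#' Per-segment limit of quantification
#'
#' @param x A \linkS4class{GeneExpressionSet}.
#' @param value Named (or column-aligned) numeric vector of LOQ values.
#' @return Named numeric vector (\code{NULL} if not yet computed).
#' @export
setMethod("loq", "GeneExpressionSet", function(x) {
  if (!"loq" %in% colnames(colData(x))) return(NULL)
  setNames(colData(x)$loq, colnames(x))
})

#' @rdname loq
#' @export
setReplaceMethod("loq", "GeneExpressionSet", function(x, value) {
  if (!is.null(names(value))) {
    miss <- setdiff(colnames(x), names(value))
    if (length(miss))
      stop("LOQ missing for segments: ", paste(miss, collapse = ", "),
           call. = FALSE)
    value <- value[colnames(x)]
  }
  colData(x)$loq <- unname(value)
  validObject(x)
  x
})

#' Q3-normalization flag
#'
#' @param x A \linkS4class{GeneExpressionSet}.
#' @return \code{TRUE} if the matrix has been Q3-normalized.
#' @export
setMethod("isNormalized", "GeneExpressionSet", function(x) {
  isTRUE(metadata(x)$normalized)
})

#' Signature name
#' @param x A \linkS4class{GeneSignature}.
#' @return Character scalar.
#' @export
setMethod("sigName", "GeneSignature", function(x) x@name)

#' Signature member genes
#' @param x A \linkS4class{GeneSignature}.
#' @return Character vector of gene symbols.
#' @export
setMethod("sigGenes", "GeneSignature", function(x) x@genes)

# internal alias so functions with an argument named `loq` can still reach
# the accessor
.getLOQ <- function(x) loq(x)

setMethod("show", "ProbeCountSet", function(object) {
  callNextMethod()
  neg <- sum(rowData(object)$negative)
  cat(sprintf("negative probes: %d of %d\n", neg, nrow(object)))
})

setMethod("show", "GeneExpressionSet", function(object) {
  callNextMethod()
  cat(sprintf("normalized (Q3): %s; LOQ: %s\n",
              isNormalized(object),
              if (is.null(loq(object))) "not computed" else "per-segment"))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' with %d genes: %s%s\n",
              object@name, length(object@genes),
              paste(head(object@genes, 5L), collapse = ", "),
              if (length(object@genes) > 5L) ", ..." else ""))
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf("SubjectProfile (%s): %d genes x %d subject columns\n",
              object@compartment, nrow(object@exprs), ncol(object@exprs)))
})
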