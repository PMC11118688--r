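#' @import SummarizedExperiment
#' @import S4Vectors
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

# closed vocabularies used by validity methods
.ARMS <- c("naive", "NAT")
.COMPARTMENTS <- c("carcinoma", "TME")
.SEGMENT_QC_REASONS <- c("raw_reads", "aligned_pct", "trimmed_pct", "stitched_pct")

#' The five-gene complement panel
#'
#' The complement genes coordinately upregulated in the tumor
#' microenvironment after neoadjuvant therapy and used for patient
#' stratification.
#'
#' @return Character vector \code{c("C3", "C1S", "C1R", "C4B", "C7")}.
#' @export
#' @examples complementPanel()
complementPanel <- function() c("C3", "C1S", "C1R", "C4B", "C7")

#' Probe-level count container for segmented spatial transcriptomics
#'
#' A \linkS4class{SummarizedExperiment} holding raw probe x segment counts.
#' Rows are probes with a \code{gene} symbol and a \code{negative} flag in
#' \code{rowData}; negative-control probes drive the per-segment limit of
#' quantification. Columns are AOI segments; segment annotation (ROI,
#' subject, compartment, treatment arm, sequencing QC metrics) lives in
#' \code{colData}.
#'
#' @export
setClass("ProbeCountSet", contains = "SummarizedExperiment")

setValidity("ProbeCountSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be finite and >= 0")
    else if (any(m != round(m)))
      msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate segment ids")
  rd <- rowData(object)
  if (!all(c("gene", "negative") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene' and 'negative'")
  else {
    if (any(is.na(rd$gene)) || any(!nzchar(rd$gene)))
      msg <- c(msg, "every probe must map to a gene symbol or negative-control class")
    if (!is.logical(rd$negative) || any(is.na(rd$negative)))
      msg <- c(msg, "'negative' must be logical without NA")
    else if (!any(rd$negative))
      msg <- c(msg, "at least one negative-control probe is required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeCountSet
#'
#' @param counts Non-negative integer matrix, probes x segments, with probe
#'   ids as rownames and segment ids as colnames.
#' @param gene Character vector mapping each probe to a gene symbol (the
#'   negative-control class counts as a symbol).
#' @param negative Logical vector flagging negative-control probes.
#' @param segmentData Optional \code{data.frame}/\code{DataFrame} of segment
#'   annotation, one row per column of \code{counts}.
#' @return A validated \linkS4class{ProbeCountSet}.
#' @export
ProbeCountSet <- function(counts, gene, negative, segmentData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  if (is.null(segmentData))
    segmentData <- S4Vectors::DataFrame(row.names = colnames(counts))
  else {
    segmentData <- S4Vectors::DataFrame(segmentData)
    if (!is.null(segmentData$segment_id))
      rownames(segmentData) <- segmentData$segment_id
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene = as.character(gene),
                                   negative = as.logical(negative),
                                   row.names = rownames(counts)),
    colData = segmentData[colnames(counts), , drop = FALSE])
  new("ProbeCountSet", se)
}

#' Gene-level expression container with per-segment LOQ
#'
#' A \linkS4class{SummarizedExperiment} of gene x segment expression values
#' (probe-collapsed raw or Q3-normalized). The per-segment limit of
#' quantification, when computed, is the \code{loq} column of \code{colData};
#' \code{metadata(x)$normalized} records whether Q3 normalization has been
#' applied (in which case every segment's third quartile equals a common
#' constant).
#'
#' @export
setClass("GeneExpressionSet", contains = "SummarizedExperiment")

setValidity("GeneExpressionSet", function(object) {
  msg <- character(0)
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- assay(object, "exprs")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "expression values must be finite and >= 0")
    norm <- metadata(object)$normalized
    if (isTRUE(norm) && ncol(m) > 1L && nrow(m) > 0L) {
      q3 <- apply(m, 2L, quantile, probs = 0.75, names = FALSE)
      if (diff(range(q3)) > 1e-9 * max(abs(q3), 1))
        msg <- c(msg, "flagged normalized but per-segment Q3 is not constant")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene symbols")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate segment ids")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneExpressionSet
#'
#' @param exprs Non-negative numeric matrix, genes x segments.
#' @param segmentData Optional segment annotation (one row per segment).
#' @param loq Optional named numeric vector of per-segment LOQ values.
#' @param normalized Logical; \code{TRUE} once Q3 normalization is applied.
#' @return A validated \linkS4class{GeneExpressionSet}.
#' @export
GeneExpressionSet <- function(exprs, segmentData = NULL, loq = NULL,
                              normalized = FALSE) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "numeric"
  if (is.null(segmentData))
    segmentData <- S4Vectors::DataFrame(row.names = colnames(exprs))
  else {
    segmentData <- S4Vectors::DataFrame(segmentData)
    if (!is.null(segmentData$segment_id))
      rownames(segmentData) <- segmentData$segment_id
  }
  segmentData <- segmentData[colnames(exprs), , drop = FALSE]
  if (!is.null(loq))
    segmentData$loq <- unname(loq[colnames(exprs)])
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = segmentData)
  metadata(se)$normalized <- isTRUE(normalized)
  new("GeneExpressionSet", se)
}

#' A named gene signature
#'
#' A gene program (CAF subtype, malignant state/lineage, immune exhaustion,
#' ...) scored by the geometric mean of its member genes.
#'
#' @slot name Signature name.
#' @slot genes Character vector of member gene symbols (unique, non-empty).
#' @export
setClass("GeneSignature",
         representation(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "gene list must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes within the signature")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSignature-class
#' @param name Signature name.
#' @param genes Character vector of member gene symbols.
#' @return A validated \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(name, genes) {
  new("GeneSignature", name = as.character(name), genes = as.character(genes))
}

#' Sparse single-cell (single-nucleus) count container
#'
#' A \linkS4class{SingleCellExperiment} with a sparse \code{counts} assay
#' (genes x cells) and mandatory \code{subject}, \code{arm} and
#' \code{cell_type} columns in \code{colData}. The treatment arm uses the
#' same closed vocabulary as the spatial data (\code{"naive"}, \code{"NAT"}).
#'
#' @export
setClass("CellCounts", contains = "SingleCellExperiment")

setValidity("CellCounts", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (min(m) < 0) msg <- c(msg, "counts must be >= 0")
  }
  cd <- colData(object)
  need <- c("subject", "arm", "cell_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  else {
    if (any(is.na(cd$subject)))
      msg <- c(msg, "every cell needs a subject")
    if (!all(cd$arm %in% .ARMS))
      msg <- c(msg, sprintf("arm must be one of {%s}", paste(.ARMS, collapse = ", ")))
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate cell ids")
  if (length(msg)) msg else TRUE
})

#' Construct a CellCounts object
#'
#' @param counts Sparse (or dense) non-negative matrix, genes x cells.
#' @param cellData \code{data.frame} with one row per cell; must contain
#'   \code{subject}, \code{arm} and \code{cell_type}.
#' @return A validated \linkS4class{CellCounts}.
#' @export
CellCounts <- function(counts, cellData) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  cellData <- S4Vectors::DataFrame(cellData)
  if (nrow(cellData) != ncol(counts))
    stop("cell annotation has ", nrow(cellData), " rows but the matrix has ",
         ncol(counts), " cells", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- if (!is.null(rownames(cellData))) rownames(cellData)
                        else sprintf("cell%05d", seq_len(ncol(counts)))
  rownames(cellData) <- colnames(counts)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cellData)
  new("CellCounts", sce)
}

#' Subject-level expression profile for one compartment
#'
#' Log2-transformed subject-wise mean expression for the carcinoma or TME
#' compartment, with subject covariates, the input to the linear-model
#' differential expression stage.
#'
#' @slot exprs Matrix of log2 subject means, genes x subjects.
#' @slot covariates \code{data.frame} of subject covariates (arm, age, sex,
#'   grade, stage, tumor_size, margin), rownames = subject ids.
#' @slot compartment \code{"carcinoma"}, \code{"TME"}, or \code{"both"}.
#' @export
setClass("SubjectProfile",
         representation(exprs = "matrix", covariates = "data.frame",
                        compartment = "character"))

setValidity("SubjectProfile", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@exprs)))
    msg <- c(msg, "subject profile values must be finite")
  if (ncol(object@exprs) != nrow(object@covariates))
    msg <- c(msg, "one covariate row per profile column is required")
  if (length(msg)) msg else TRUE
})
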