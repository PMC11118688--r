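#' @importFrom Matrix sparseMatrix writeMM colSums rowMeans t
NULL

.SEGMENT_COLUMNS <- c("segment_id", "roi_id", "subject_id", "compartment",
                      "arm", "raw_reads", "aligned_pct", "trimmed_pct",
                      "stitched_pct")
.SUBJECT_COVARIATES <- c("age", "sex", "grade", "stage", "tumor_size", "margin")

.validateSegmentTable <- function(seg, segment_ids = NULL) {
  seg <- as.data.frame(seg)
  if (is.null(seg$segment_id) && !is.null(rownames(seg)))
    seg$segment_id <- rownames(seg)
  miss <- setdiff(.SEGMENT_COLUMNS, colnames(seg))
  if (length(miss))
    stop("segment table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- seg$segment_id[duplicated(seg$segment_id)]
  if (length(dup))
    stop("duplicate segment ids in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!all(seg$compartment %in% .COMPARTMENTS))
    stop("compartment must be one of {",
         paste(.COMPARTMENTS, collapse = ", "), "}", call. = FALSE)
  if (!all(seg$arm %in% .ARMS))
    stop("arm must be one of {", paste(.ARMS, collapse = ", "), "}",
         call. = FALSE)
  pct <- as.matrix(seg[, c("aligned_pct", "trimmed_pct", "stitched_pct")])
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("percent QC metrics must lie in [0, 100]", call. = FALSE)
  if (!is.null(segment_ids)) {
    absent <- setdiff(segment_ids, seg$segment_id)
    if (length(absent))
      stop("segments missing from annotation: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  rownames(seg) <- seg$segment_id
  seg
}

#' Read a probe-level count matrix from TSV
#'
#' The file has a header of \code{probe_id}, \code{gene_symbol} and one
#' column per segment; probes whose gene symbol starts with
#' \code{neg_prefix} are flagged as negative-control probes.
#'
#' @param path Path to the tab-separated count file.
#' @param neg_prefix Prefix identifying negative-control probes
#'   (default \code{"NegProbe"}).
#' @return A \linkS4class{ProbeCountSet}.
#' @export
readProbeCounts <- function(path, neg_prefix = "NegProbe") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || !identical(colnames(tab)[1:2], c("probe_id", "gene_symbol")))
    stop("expected columns 'probe_id', 'gene_symbol' then segment ids in ",
         path, call. = FALSE)
  segs <- colnames(tab)[-(1:2)]
  dup <- segs[duplicated(segs)]
  if (length(dup))
    stop("duplicated segment column(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- tab$probe_id[duplicated(tab$probe_id)]
  if (length(dup))
    stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at probe '%s', segment '%s'",
                 tab$probe_id[bad[1L, 1L]], segs[bad[1L, 2L]]), call. = FALSE)
  rownames(counts) <- tab$probe_id
  ProbeCountSet(counts, gene = tab$gene_symbol,
                negative = startsWith(tab$gene_symbol, neg_prefix))
}

#' Write a probe-level count matrix to TSV
#'
#' Inverse of \code{\link{readProbeCounts}}.
#'
#' @param pcm A \linkS4class{ProbeCountSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeProbeCounts <- function(pcm, path) {
  stopifnot(is(pcm, "ProbeCountSet"))
  out <- data.frame(probe_id = rownames(pcm),
                    gene_symbol = rowData(pcm)$gene,
                    assay(pcm, "counts"), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segment annotation from TSV
#'
#' Required columns: segment_id, roi_id, subject_id, compartment
#' (carcinoma/TME), arm (naive/NAT), raw_reads, aligned_pct, trimmed_pct,
#' stitched_pct; subject covariates (age, sex, grade, stage, tumor_size,
#' margin) are carried through when present.
#'
#' @param path Path to the tab-separated annotation file.
#' @return Validated \code{data.frame}, rownames = segment ids.
#' @export
readSegmentAnnotation <- function(path) {
  .validateSegmentTable(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a subject survival table from TSV
#'
#' Columns: subject_id, time_months (> 0), event (1 death / 0 censored),
#' plus covariates.
#'
#' @param path Path to the tab-separated survival file.
#' @return Validated \code{data.frame}, one row per subject.
#' @export
readSurvivalTable <- function(path) {
  surv <- read.delim(path, stringsAsFactors = FALSE)
  .validateSurvivalTable(surv)
}

.validateSurvivalTable <- function(surv) {
  surv <- as.data.frame(surv)
  miss <- setdiff(c("subject_id", "time_months", "event"), colnames(surv))
  if (length(miss))
    stop("survival table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(surv$subject_id))
    stop("more than one survival record per subject", call. = FALSE)
  if (any(!is.finite(surv$time_months)) || any(surv$time_months <= 0))
    stop("time_months must be > 0", call. = FALSE)
  if (!all(surv$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  rownames(surv) <- surv$subject_id
  surv
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then member genes. Duplicate
#' genes within a line are dropped with a warning; a line with no genes is
#' an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of \linkS4class{GeneSignature} objects (empty list for
#'   an empty file).
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("gene set '", f[1L], "' has an empty gene list", call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("gene set '", f[1L], "' has an empty gene list", call. = FALSE)
    if (anyDuplicated(genes)) {
      warning("dropping duplicated gene(s) in set '", f[1L], "'",
              call. = FALSE)
      genes <- unique(genes)
    }
    GeneSignature(f[1L], genes)
  })
  names(sets) <- vapply(sets, sigName, character(1))
  sets
}

#' Write gene signatures to a GMT file
#'
#' @param sets List of \linkS4class{GeneSignature} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(sigName(s), ".", sigGenes(s)), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse single-cell count matrix (MatrixMarket triplets)
#'
#' The MTX file stores genes as rows and cells as columns in the standard
#' 1-based coordinate dialect. \code{cells_path} is a TSV with one row per
#' cell (columns \code{cell_id}, \code{subject}, \code{arm},
#' \code{cell_type}, optional \code{subtype}); \code{genes_path} a TSV with
#' one row per gene (column \code{gene_id}).
#'
#' @param matrix_path Path to the MTX triplet file.
#' @param cells_path Path to the cell annotation TSV.
#' @param genes_path Path to the gene annotation TSV.
#' @return A \linkS4class{CellCounts}.
#' @export
readSparseCells <- function(matrix_path, cells_path, genes_path) {
  lines <- readLines(matrix_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (!length(lines))
    stop("no dimension header in ", matrix_path, call. = FALSE)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  if (length(hdr) != 3L)
    stop("malformed MTX dimension line in ", matrix_path, call. = FALSE)
  ng <- hdr[1L]; nc <- hdr[2L]; nnz <- hdr[3L]
  trip <- if (length(lines) > 1L)
    matrix(scan(text = lines[-1L], quiet = TRUE), ncol = 3L, byrow = TRUE)
  else matrix(numeric(0), ncol = 3L)
  if (nrow(trip) != nnz)
    stop("MTX header promises ", nnz, " entries but ", nrow(trip),
         " were found", call. = FALSE)
  if (nnz > 0) {
    if (min(trip[, 1L]) < 1 || max(trip[, 1L]) > ng)
      stop("MTX gene index out of range [1, ", ng, "]", call. = FALSE)
    if (min(trip[, 2L]) < 1 || max(trip[, 2L]) > nc)
      stop("MTX cell index out of range [1, ", nc, "]", call. = FALSE)
    if (any(trip[, 3L] < 0))
      stop("negative count in MTX triplets", call. = FALSE)
  }
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)
  cells <- read.delim(cells_path, stringsAsFactors = FALSE)
  if (nrow(genes) != ng)
    stop("gene annotation has ", nrow(genes), " rows but the matrix has ",
         ng, " genes", call. = FALSE)
  if (nrow(cells) != nc)
    stop("cell annotation has ", nrow(cells), " rows but the matrix has ",
         nc, " cells", call. = FALSE)
  m <- sparseMatrix(i = trip[, 1L], j = trip[, 2L], x = trip[, 3L],
                    dims = c(ng, nc))
  rownames(m) <- genes$gene_id
  if (!is.null(cells$cell_id)) rownames(cells) <- cells$cell_id
  CellCounts(m, cells)
}

#' Write a CellCounts object as MTX + annotation TSVs
#'
#' Inverse of \code{\link{readSparseCells}}.
#'
#' @param cm A \linkS4class{CellCounts}.
#' @param matrix_path,cells_path,genes_path Output paths.
#' @return \code{matrix_path}, invisibly.
#' @export
writeSparseCells <- function(cm, matrix_path, cells_path, genes_path) {
  stopifnot(is(cm, "CellCounts"))
  Matrix::writeMM(assay(cm, "counts"), matrix_path)
  cells <- as.data.frame(colData(cm))
  cells <- cbind(cell_id = colnames(cm), cells)
  write.table(cells, cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(cm)), genes_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Write a gene-level expression matrix to TSV
#'
#' @param em A \linkS4class{GeneExpressionSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(em, path) {
  stopifnot(is(em, "GeneExpressionSet"))
  out <- data.frame(gene = rownames(em), assay(em, "exprs"),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration with workflow defaults
#'
#' Returns the full default configuration (QC thresholds, model covariates,
#' stratification and single-cell settings) optionally overridden by a YAML
#' file. Every pipeline run should log this object together with the RNG
#' seed.
#'
#' @param path Optional YAML file whose keys override the defaults.
#' @return Nested named list of configuration values.
#' @export
readAnalysisConfig <- function(path = NULL) {
  cfg <- list(
    qc = unclass(qcThresholds()),
    de = list(covariates = c("age", "sex", "grade", "stage"),
              alpha = 0.05, fdr = FALSE),
    stratify = list(panel = complementPanel(), linkage = "ward.D2",
                    log2_scale = TRUE),
    survival = list(covariates = c("subgroup", "age", "sex", "tumor_size",
                                   "grade", "margin")),
    sc = list(target_sum = 1e4, direction = "greater")
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}
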