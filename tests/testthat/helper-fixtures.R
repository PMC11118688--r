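suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(Matrix)
})

extdata <- function(f) system.file("extdata", f, package = "SpatialComplement")

# small random ProbeCountSet with valid annotation, for round-trip and
# property tests
randomProbeSet <- function(n_genes = 6, n_neg = 3, n_seg = 4,
                           probes_per_gene = 2, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  probe_gene <- c(rep(genes, each = probes_per_gene),
                  sprintf("NegProbe%d", seq_len(n_neg)))
  probe_ids <- c(paste0(rep(genes, each = probes_per_gene), "_p",
                        seq_len(probes_per_gene)),
                 sprintf("NegProbe%d", seq_len(n_neg)))
  segs <- sprintf("S%02d", seq_len(n_seg))
  counts <- matrix(rnbinom(length(probe_ids) * n_seg, mu = 30, size = 5),
                   nrow = length(probe_ids),
                   dimnames = list(probe_ids, segs))
  ProbeCountSet(counts, gene = probe_gene,
                negative = startsWith(probe_gene, "NegProbe"),
                segmentData = toySegTable(segs))
}

toySegTable <- function(segment_ids, compartment = NULL, subject = NULL,
                        arm = NULL) {
  n <- length(segment_ids)
  data.frame(
    segment_id = segment_ids,
    roi_id = paste0("R", seq_len(n)),
    subject_id = if (is.null(subject)) paste0("P", rep_len(1:2, n)) else subject,
    compartment = if (is.null(compartment)) rep_len(c("carcinoma", "TME"), n)
                  else compartment,
    arm = if (is.null(arm)) rep_len(c("naive", "NAT"), n) else arm,
    raw_reads = 1e5, aligned_pct = 95, trimmed_pct = 95, stitched_pct = 95,
    age = rep_len(c(60, 70), n), sex = rep_len(c("M", "F"), n),
    grade = rep_len(c("G1", "G2"), n), stage = rep_len(1:2, n),
    tumor_size = 3, margin = rep_len(c("R0", "R1"), n),
    row.names = segment_ids, stringsAsFactors = FALSE)
}

# expression set with explicit values and annotation
makeExprSet <- function(vals, compartment = NULL, subject = NULL,
                        arm = NULL, loq = NULL) {
  GeneExpressionSet(vals,
                    segmentData = toySegTable(colnames(vals), compartment,
                                              subject, arm),
                    loq = loq)
}

# SubjectProfile built directly from a log2 matrix and an arm vector
makeProfile <- function(Y, arm, covs = NULL) {
  subjects <- colnames(Y)
  covdf <- data.frame(subject_id = subjects, arm = arm,
                      row.names = subjects, stringsAsFactors = FALSE)
  if (!is.null(covs)) covdf <- cbind(covdf, covs)
  new("SubjectProfile", exprs = Y, covariates = covdf, compartment = "TME")
}

# minimal CellCounts with a given counts matrix (genes x cells)
makeCells <- function(counts, subject, arm, cell_type = "CAF",
                      subtype = NA_character_) {
  CellCounts(counts,
             cellData = data.frame(subject = subject, arm = arm,
                                   cell_type = rep_len(cell_type, ncol(counts)),
                                   subtype = rep_len(subtype, ncol(counts)),
                                   row.names = colnames(counts),
                                   stringsAsFactors = FALSE))
}
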