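#' QC thresholds with workflow defaults
#'
#' Thresholds for segment QC, LOQ computation and detection filtering.
#' Defaults follow the standard GeoMx-NGS workflow: segments need at least
#' 1,000 raw reads and at least 80\% aligned/trimmed/stitched rates; the
#' per-segment LOQ is the geometric mean of the negative probes times their
#' geometric SD squared, floored at 2; segments must detect at least 1\% of
#' genes and genes must be detected in at least 5\% of segments.
#'
#' @param min_raw_reads Minimum raw sequencing reads per segment.
#' @param min_pct Minimum aligned/trimmed/stitched percentage.
#' @param loq_sd_exponent Exponent on the negative-probe geometric SD.
#' @param loq_floor Lower bound on the LOQ.
#' @param min_segment_detection_rate Minimum fraction of genes a segment
#'   must detect.
#' @param min_gene_detection_rate Minimum fraction of segments a gene must
#'   be detected in.
#' @param probe_zero_floor Floor applied to counts before geometric means.
#' @return Object of class \code{QCThresholds} (a validated list).
#' @export
qcThresholds <- function(min_raw_reads = 1000, min_pct = 80,
                         loq_sd_exponent = 2, loq_floor = 2,
                         min_segment_detection_rate = 0.01,
                         min_gene_detection_rate = 0.05,
                         probe_zero_floor = 0.5) {
  th <- list(min_raw_reads = min_raw_reads, min_pct = min_pct,
             loq_sd_exponent = loq_sd_exponent, loq_floor = loq_floor,
             min_segment_detection_rate = min_segment_detection_rate,
             min_gene_detection_rate = min_gene_detection_rate,
             probe_zero_floor = probe_zero_floor)
  for (nm in names(th)) .assertScalarNumber(th[[nm]], nm)
  for (nm in c("min_segment_detection_rate", "min_gene_detection_rate"))
    if (th[[nm]] >= 1)
      stop("'", nm, "' must lie in (0, 1)", call. = FALSE)
  structure(th, class = "QCThresholds")
}

.asThresholds <- function(th) {
  if (inherits(th, "QCThresholds")) return(th)
  do.call(qcThresholds, as.list(th))
}

#' Segment-level quality control
#'
#' Drops segments with fewer than \code{min_raw_reads} raw reads or with an
#' aligned, trimmed or stitched percentage below \code{min_pct}. (The
#' workflow convention is that low-read segments fail; the read threshold
#' is configurable.)
#'
#' @param pcm A \linkS4class{ProbeCountSet}.
#' @param seg Segment annotation \code{data.frame}; defaults to
#'   \code{segmentData(pcm)}. Every column of \code{pcm} must be annotated.
#' @param th \code{\link{qcThresholds}}.
#' @return List with \code{counts} (the filtered \code{ProbeCountSet}) and
#'   \code{report} (removed segments with reason codes drawn from
#'   raw_reads/aligned_pct/trimmed_pct/stitched_pct).
#' @export
segmentQC <- function(pcm, seg = segmentData(pcm), th = qcThresholds()) {
  stopifnot(is(pcm, "ProbeCountSet"))
  th <- .asThresholds(th)
  seg <- .validateSegmentTable(seg, segment_ids = colnames(pcm))
  seg <- seg[colnames(pcm), , drop = FALSE]
  checks <- cbind(raw_reads = seg$raw_reads < th$min_raw_reads,
                  aligned_pct = seg$aligned_pct < th$min_pct,
                  trimmed_pct = seg$trimmed_pct < th$min_pct,
                  stitched_pct = seg$stitched_pct < th$min_pct)
  fail <- rowSums(checks) > 0
  removed <- data.frame(
    segment_id = seg$segment_id[fail],
    reason = apply(checks[fail, , drop = FALSE], 1L, function(z)
      paste(.SEGMENT_QC_REASONS[z], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  if (all(fail)) stop("no segments survive QC", call. = FALSE)
  list(counts = pcm[, !fail], report = list(removed_segments = removed))
}

#' Within-gene probe QC (optional)
#'
#' Flags low-performing probes of multi-probe genes: within a gene, a probe
#' whose geometric-mean count across segments falls below \code{min_ratio}
#' of the gene's average probe geometric mean is dropped. This is an
#' interpretation of standard probe QC and is off by default for
#' single-probe panels.
#'
#' @param pcm A \linkS4class{ProbeCountSet}.
#' @param min_ratio Minimum acceptable ratio (default 0.1).
#' @param floor Floor applied before geometric means.
#' @return List with \code{counts} (filtered set, negative probes
#'   untouched) and \code{removed_probes}.
#' @export
probeQC <- function(pcm, min_ratio = 0.1, floor = 0.5) {
  stopifnot(is(pcm, "ProbeCountSet"))
  counts <- assay(pcm, "counts")
  gene <- rowData(pcm)$gene
  neg <- rowData(pcm)$negative
  gm <- exp(rowMeans(log(pmax(counts, floor))))
  drop <- rep(FALSE, nrow(pcm))
  for (g in unique(gene[!neg])) {
    idx <- which(gene == g & !neg)
    if (length(idx) < 2L) next
    drop[idx] <- gm[idx] < min_ratio * mean(gm[idx])
    if (all(drop[idx])) drop[idx] <- FALSE  # never orphan a gene
  }
  list(counts = pcm[!drop, ], removed_probes = rownames(pcm)[drop])
}

#' Collapse probes to gene-level expression by geometric mean
#'
#' Per gene and segment, the value is the geometric mean over that gene's
#' probes of \code{max(count, floor)}. Negative-control probes are excluded
#' from gene rows; compute the per-segment LOQ from the probe-level object
#' (\code{\link{computeLOQ}}) before or after collapsing.
#'
#' @param pcm A \linkS4class{ProbeCountSet}.
#' @param floor Positive floor applied to counts (default 0.5).
#' @return A \linkS4class{GeneExpressionSet} of gene x segment values.
#' @export
collapseProbes <- function(pcm, floor = 0.5) {
  stopifnot(is(pcm, "ProbeCountSet"))
  .assertScalarNumber(floor, "floor")
  keep <- !rowData(pcm)$negative
  gene <- rowData(pcm)$gene[keep]
  lcounts <- log(pmax(assay(pcm, "counts")[keep, , drop = FALSE], floor))
  genes <- unique(gene)
  sums <- rowsum(lcounts, group = gene, reorder = FALSE)
  vals <- exp(sums / as.vector(table(factor(gene, levels = rownames(sums)))))
  GeneExpressionSet(vals[genes, , drop = FALSE],
                    segmentData = colData(pcm))
}

#' Per-segment limit of quantification from negative-control probes
#'
#' \code{LOQ(s) = max(loq_floor, GM_neg(s) * GSD_neg(s)^loq_sd_exponent)}
#' where GM is the geometric mean of the floored negative-probe counts and
#' GSD the geometric standard deviation (exp of the sample SD of their
#' natural logs). Segments with fewer than two negative probes fall back to
#' the floor via GSD = 1.
#'
#' @param pcm A \linkS4class{ProbeCountSet}.
#' @param th \code{\link{qcThresholds}}.
#' @return Named numeric vector, segment id -> LOQ.
#' @export
computeLOQ <- function(pcm, th = qcThresholds()) {
  stopifnot(is(pcm, "ProbeCountSet"))
  th <- .asThresholds(th)
  negs <- assay(pcm, "counts")[rowData(pcm)$negative, , drop = FALSE]
  vapply(colnames(pcm), function(s) {
    v <- negs[, s]
    max(th$loq_floor,
        geomMean(v, th$probe_zero_floor) *
          geomSD(v, th$probe_zero_floor) ^ th$loq_sd_exponent)
  }, numeric(1))
}

#' Detection-rate filtering against the per-segment LOQ
#'
#' A gene is detected in a segment when its value strictly exceeds that
#' segment's LOQ. Segments detecting fewer than
#' \code{min_segment_detection_rate} of genes are removed first; genes
#' detected in fewer than \code{min_gene_detection_rate} of the surviving
#' segments are removed second.
#'
#' @param em A \linkS4class{GeneExpressionSet}.
#' @param loq Named per-segment LOQ vector; defaults to \code{loq(em)}.
#' @param th \code{\link{qcThresholds}}.
#' @return List with \code{exprs} (the filtered set, LOQ attached) and
#'   \code{report} (removed segments/genes and per-segment detection rates).
#' @export
detectionFilter <- function(em, loq = NULL, th = qcThresholds()) {
  stopifnot(is(em, "GeneExpressionSet"))
  th <- .asThresholds(th)
  if (is.null(loq)) loq <- .getLOQ(em)
  if (is.null(loq))
    stop("no LOQ available: pass 'loq' or attach it with loq<-", call. = FALSE)
  miss <- setdiff(colnames(em), names(loq))
  if (length(miss))
    stop("LOQ undefined for segments: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- assay(em, "exprs")
  det <- sweep(vals, 2L, loq[colnames(em)], ">")
  seg_rate <- colMeans(det)
  seg_keep <- seg_rate >= th$min_segment_detection_rate
  det <- det[, seg_keep, drop = FALSE]
  gene_rate <- rowMeans(det)
  gene_keep <- gene_rate >= th$min_gene_detection_rate
  if (!any(seg_keep) || !any(gene_keep))
    stop("detection filter removed everything", call. = FALSE)
  out <- GeneExpressionSet(vals[gene_keep, seg_keep, drop = FALSE],
                           segmentData = colData(em)[seg_keep, , drop = FALSE],
                           loq = loq[colnames(em)[seg_keep]])
  list(exprs = out,
       report = list(removed_segments = colnames(em)[!seg_keep],
                     removed_genes = rownames(em)[!gene_keep],
                     segment_detection_rate = seg_rate,
                     gene_detection_rate = gene_rate))
}

#' Q3 (third-quartile) normalization
#'
#' Each segment is divided by \code{Q3(s) / GM(Q3)} where GM is the
#' geometric mean of the per-segment third quartiles, so that after
#' normalization every segment's Q3 equals the geometric mean of the
#' original Q3 values. Re-running on normalized output is the identity.
#'
#' @param em A \linkS4class{GeneExpressionSet} in which every segment has a
#'   positive third quartile.
#' @return The normalized \linkS4class{GeneExpressionSet} (flag set; the
#'   scaling factors are in \code{metadata(x)$q3_factors}).
#' @export
q3Normalize <- function(em) {
  stopifnot(is(em, "GeneExpressionSet"))
  vals <- assay(em, "exprs")
  q3 <- apply(vals, 2L, quantile, probs = 0.75, names = FALSE)
  bad <- colnames(em)[q3 <= 0]
  if (length(bad))
    stop("segment(s) with non-positive Q3: ", paste(bad, collapse = ", "),
         call. = FALSE)
  factors <- q3 / exp(mean(log(q3)))
  out <- GeneExpressionSet(sweep(vals, 2L, factors, "/"),
                           segmentData = colData(em),
                           loq = loq(em), normalized = TRUE)
  metadata(out)$q3_factors <- setNames(factors, colnames(em))
  out
}
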