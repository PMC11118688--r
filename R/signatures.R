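#' Geometric-mean signature score per segment
#'
#' Per segment, the geometric mean of the floored expression of the
#' signature genes present in the matrix. At least \code{min_present} of
#' the signature must be present; missing genes are recorded in the
#' provenance attributes and trigger a warning.
#'
#' Scores over user-supplied marker sets are signature scores, not cell
#' fractions: no deconvolution is performed.
#'
#' @param em A (normalized) \linkS4class{GeneExpressionSet}.
#' @param sig A \linkS4class{GeneSignature}.
#' @param min_present Minimum fraction of signature genes that must be
#'   present (default 0.5).
#' @param floor Floor applied before the geometric mean (default 0.5).
#' @return Named numeric vector of per-segment scores with attributes
#'   \code{genes_used} and \code{genes_missing}.
#' @export
scoreSignature <- function(em, sig, min_present = 0.5, floor = 0.5) {
  stopifnot(is(em, "GeneExpressionSet"), is(sig, "GeneSignature"))
  genes <- sigGenes(sig)
  present <- intersect(genes, rownames(em))
  missing <- setdiff(genes, present)
  if (length(present) / length(genes) < min_present)
    stop("signature '", sigName(sig), "': too few genes present; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing))
    warning("signature '", sigName(sig), "': scoring without ",
            paste(missing, collapse = ", "), call. = FALSE)
  vals <- assay(em, "exprs")[present, , drop = FALSE]
  scores <- exp(colMeans(log(pmax(vals, floor))))
  attr(scores, "genes_used") <- present
  attr(scores, "genes_missing") <- missing
  scores
}

#' Score a collection of signatures
#'
#' @param em A \linkS4class{GeneExpressionSet}.
#' @param sigs List of \linkS4class{GeneSignature} objects (e.g. from
#'   \code{\link{readGeneSets}}).
#' @param ... Passed to \code{\link{scoreSignature}}.
#' @return Object of class \code{ScoreTable}: a segments x signatures
#'   matrix with a \code{provenance} attribute listing used/missing genes
#'   per signature.
#' @export
scoreSignatures <- function(em, sigs, ...) {
  cols <- lapply(sigs, function(s) scoreSignature(em, s, ...))
  scores <- do.call(cbind, lapply(cols, as.vector))
  rownames(scores) <- colnames(em)
  colnames(scores) <- vapply(sigs, sigName, character(1))
  attr(scores, "provenance") <- lapply(cols, function(x)
    list(genes_used = attr(x, "genes_used"),
         genes_missing = attr(x, "genes_missing")))
  class(scores) <- c("ScoreTable", class(scores))
  scores
}

#' Association of signature scores with treatment arm or subgroup
#'
#' Signature scores are averaged per subject on the linear scale, log2
#' transformed, and regressed on the group indicator plus covariates with
#' the same linear-model machinery as the differential expression stage.
#'
#' @param scores A \code{ScoreTable} (segments x signatures) from
#'   \code{\link{scoreSignatures}}, or any such matrix.
#' @param seg Segment annotation covering the score rows.
#' @param grouping \code{"arm"} (NAT vs naive) or \code{"subgroup"}
#'   (high vs low complement; requires \code{subgroup}).
#' @param covariates Covariates to adjust for.
#' @param subgroup Named subject -> {"high","low"} labels (from
#'   \code{\link{stratifyComplement}}) when \code{grouping = "subgroup"}.
#' @param compartment Which compartment's segments to score (default TME).
#' @param floor Floor before log2.
#' @return \code{data.frame} with signature, estimate, se, p_value.
#' @export
scoreAssociation <- function(scores, seg, grouping = c("arm", "subgroup"),
                             covariates = c("age", "sex", "grade", "stage"),
                             subgroup = NULL, compartment = "TME",
                             floor = 0.5) {
  grouping <- match.arg(grouping)
  scores <- unclass(scores)
  seg <- .validateSegmentTable(seg, segment_ids = rownames(scores))
  seg <- seg[rownames(scores), , drop = FALSE]
  em <- GeneExpressionSet(t(scores), segmentData = seg)
  sp <- subjectAverage(em, seg, compartment = compartment, floor = floor)
  covdf <- sp@covariates
  if (grouping == "arm") {
    group <- as.numeric(covdf$arm == "NAT")
  } else {
    if (is.null(subgroup))
      stop("grouping = 'subgroup' requires subgroup labels", call. = FALSE)
    labs <- subgroup[rownames(covdf)]
    if (any(is.na(labs)))
      stop("subgroup label missing for subject(s): ",
           paste(rownames(covdf)[is.na(labs)], collapse = ", "),
           call. = FALSE)
    group <- as.numeric(labs == "high")
  }
  if (length(unique(group)) < 2L || min(table(group)) < 2L)
    stop("at least two subjects per group are required", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, group = group,
             .codeCovariates(covdf, covariates))
  .checkFullRank(X)
  out <- .fitRowsOLS(sp@exprs, X, "group")
  data.frame(signature = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Over-representation analysis with the EASE modification
#'
#' Upper-tail hypergeometric test of a query gene list against each set,
#' within a fixed gene universe (by default the genes surviving the
#' detection filter). With \code{ease = TRUE} the overlap is reduced by one
#' (the conservative EASE score convention); Benjamini-Hochberg FDR is
#' computed across sets.
#'
#' @param query Character vector of query genes (subset of the universe).
#' @param universe Character vector defining the sampled gene space.
#' @param sets List of \linkS4class{GeneSignature} objects; each set is
#'   intersected with the universe.
#' @param ease Apply the EASE k-1 modification (default TRUE).
#' @return \code{data.frame} with set, k (overlap), m (set size in
#'   universe), q (query size), N (universe size), p_value and fdr, ordered
#'   by p.
#' @export
enrichmentORA <- function(query, universe, sets, ease = TRUE) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("empty query gene list", call. = FALSE)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query gene(s) outside the universe: ",
         paste(head(out, 5L), collapse = ", "), call. = FALSE)
  N <- length(universe)
  q <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(sigGenes(s), universe)
    m <- length(members)
    k <- length(intersect(members, query))
    kp <- if (ease) max(k - 1L, 0L) else k
    p <- phyper(kp - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(set = sigName(s), k = k, m = m, q = q, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- p.adjust(res$p_value, "BH")
  res[order(res$p_value, res$set), , drop = FALSE]
}
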