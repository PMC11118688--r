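#' @importFrom lme4 lmer glmer fixef VarCorr glmerControl lmerControl
NULL

#' Library-size normalization and log2 transform for single-cell counts
#'
#' Adds a \code{logcounts} assay: \code{log2(1 + counts * target_sum /
#' library_size)} per cell. Cells with zero total count get zeros.
#'
#' @param cm A \linkS4class{CellCounts}.
#' @param target_sum Target library size (default 10,000).
#' @return \code{cm} with a \code{logcounts} assay.
#' @export
normalizeCells <- function(cm, target_sum = 1e4) {
  stopifnot(is(cm, "CellCounts"))
  counts <- assay(cm, "counts")
  libs <- Matrix::colSums(counts)
  fac <- ifelse(libs > 0, target_sum / libs, 0)
  norm <- counts %*% Matrix::Diagonal(x = fac)
  norm@x <- log2(1 + norm@x)
  dimnames(norm) <- dimnames(counts)
  assay(cm, "logcounts") <- norm
  cm
}

# resolve a cell subset given as logical vector, cell ids, or a predicate
# on colData
.resolveCells <- function(cm, cell_subset) {
  if (is.null(cell_subset)) return(colnames(cm))
  if (is.function(cell_subset)) {
    keep <- cell_subset(as.data.frame(colData(cm)))
    return(colnames(cm)[keep])
  }
  if (is.logical(cell_subset)) return(colnames(cm)[cell_subset])
  intersect(as.character(cell_subset), colnames(cm))
}

#' Assign cell subtypes by signature vs rank-matched background score
#'
#' For each subtype signature, a cell's signature score is the mean of the
#' log2-normalized expression of the signature genes; the background score
#' uses a matched background set: for each signature gene, the
#' non-signature gene whose across-cell mean-expression rank is nearest
#' (ties to the lower rank, chosen without replacement; signature genes of
#' all subtypes are excluded from candidacy). A cell is assigned a subtype
#' whenever its signature score strictly exceeds its background score, so
#' a cell may carry several labels (\code{mode = "single"} keeps only the
#' subtype with the largest score margin).
#'
#' @param cm A \linkS4class{CellCounts} with a \code{logcounts} assay (see
#'   \code{\link{normalizeCells}}).
#' @param sigs List of \linkS4class{GeneSignature} objects, one per subtype.
#' @param cell_subset Cells to evaluate: logical vector, cell ids, or a
#'   predicate on the cell metadata (default all cells).
#' @param mode \code{"multi"} (default) or \code{"single"}.
#' @param assay Assay to score (default \code{"logcounts"}).
#' @return List of class \code{CellAssignment}: \code{assigned} (cells x
#'   subtypes logical matrix), \code{sig_scores}, \code{bg_scores},
#'   \code{background} (matched gene sets), and \code{labels} (per-cell
#'   character vector in single mode, else list of labels).
#' @export
assignSubtypes <- function(cm, sigs, cell_subset = NULL,
                           mode = c("multi", "single"),
                           assay = "logcounts") {
  stopifnot(is(cm, "CellCounts"))
  mode <- match.arg(mode)
  cells <- .resolveCells(cm, cell_subset)
  if (!length(cells)) stop("empty cell subset", call. = FALSE)
  M <- SummarizedExperiment::assay(cm, assay)[, cells, drop = FALSE]
  all_sig_genes <- unique(unlist(lapply(sigs, sigGenes)))
  miss <- setdiff(all_sig_genes, rownames(M))
  if (length(miss))
    stop("signature gene(s) absent: ", paste(head(miss, 5L), collapse = ", "),
         call. = FALSE)
  mu <- Matrix::rowMeans(M)
  # deterministic ranks: ties broken by gene order
  rk <- rank(mu, ties.method = "first")
  candidates <- setdiff(rownames(M), all_sig_genes)
  sig_scores <- bg_scores <- matrix(
    NA_real_, length(cells), length(sigs),
    dimnames = list(cells, vapply(sigs, sigName, character(1))))
  background <- vector("list", length(sigs))
  names(background) <- colnames(sig_scores)
  for (i in seq_along(sigs)) {
    genes <- sigGenes(sigs[[i]])
    if (length(candidates) < length(genes))
      stop("fewer candidate background genes (", length(candidates),
           ") than signature genes (", length(genes), ") for subtype '",
           sigName(sigs[[i]]), "'", call. = FALSE)
    avail <- candidates
    bg <- character(length(genes))
    for (j in seq_along(genes)) {
      d <- abs(rk[avail] - rk[genes[j]])
      # nearest rank; among equidistant candidates take the lower rank
      best <- avail[order(d, rk[avail])][1L]
      bg[j] <- best
      avail <- setdiff(avail, best)
    }
    background[[i]] <- bg
    sig_scores[, i] <- Matrix::colMeans(M[genes, , drop = FALSE])
    bg_scores[, i] <- Matrix::colMeans(M[bg, , drop = FALSE])
  }
  assigned <- sig_scores > bg_scores
  labels <- if (mode == "single") {
    margin <- sig_scores - bg_scores
    lab <- colnames(assigned)[apply(margin, 1L, which.max)]
    lab[rowSums(assigned) == 0] <- NA_character_
    setNames(lab, cells)
  } else {
    apply(assigned, 1L, function(z) colnames(assigned)[z], simplify = FALSE)
  }
  structure(list(assigned = assigned, sig_scores = sig_scores,
                 bg_scores = bg_scores, background = background,
                 labels = labels),
            class = "CellAssignment")
}

#' Flag high-expression cells of one gene
#'
#' The cutoff is the median of the gene's non-zero expression over the
#' pooled evaluation population (pooling the arms keeps the per-arm
#' percentages comparable); a cell is flagged when its expression strictly
#' exceeds the cutoff.
#'
#' @param cm A \linkS4class{CellCounts}.
#' @param gene Gene symbol.
#' @param population Cells defining the cutoff population (logical, ids,
#'   or predicate; default all cells).
#' @param assay Assay to use (default \code{"logcounts"}).
#' @return List of class \code{HighExpressionFlags}: \code{gene},
#'   \code{cutoff}, \code{flags} (named logical over the population).
#' @export
flagHighExpression <- function(cm, gene, population = NULL,
                               assay = "logcounts") {
  stopifnot(is(cm, "CellCounts"))
  if (!gene %in% rownames(cm))
    stop("gene '", gene, "' not present", call. = FALSE)
  cells <- .resolveCells(cm, population)
  v <- as.numeric(SummarizedExperiment::assay(cm, assay)[gene, cells])
  names(v) <- cells
  nz <- v[v > 0]
  if (!length(nz))
    stop("gene '", gene, "' has no non-zero cell in the population",
         call. = FALSE)
  cutoff <- median(nz)
  structure(list(gene = gene, cutoff = cutoff, flags = v > cutoff),
            class = "HighExpressionFlags")
}

.oneTailedP <- function(est, se, direction = "greater") {
  z <- est / se
  two <- 2 * pnorm(-abs(z))
  hyp <- if (direction == "greater") est > 0 else est < 0
  list(two = two, one = if (hyp) two / 2 else 1 - two / 2)
}

#' Linear mixed-model test of gene expression between arms
#'
#' \code{log2 expression ~ treatment + (1 | subject)} over the selected
#' cells (REML); the one-tailed p tests the pre-registered direction
#' (treated above naive by default) via the Wald statistic. With zero
#' within-subject variance the model degenerates to a pooled t-test on
#' subject means, which is then reported.
#'
#' @param cm A \linkS4class{CellCounts} with \code{logcounts}.
#' @param gene Gene symbol.
#' @param cell_subset Cells to include (logical, ids, or predicate).
#' @param direction \code{"greater"} (NAT > naive, default) or
#'   \code{"less"}.
#' @param assay Assay to model (default \code{"logcounts"}).
#' @return List with estimate (log2 NAT - naive), se, p_one_tailed,
#'   p_two_tailed, and the method used.
#' @export
lmmExpressionTest <- function(cm, gene, cell_subset = NULL,
                              direction = c("greater", "less"),
                              assay = "logcounts") {
  stopifnot(is(cm, "CellCounts"))
  direction <- match.arg(direction)
  cells <- .resolveCells(cm, cell_subset)
  if (!gene %in% rownames(cm))
    stop("gene '", gene, "' not present", call. = FALSE)
  cd <- as.data.frame(colData(cm))[cells, , drop = FALSE]
  dat <- data.frame(
    y = as.numeric(SummarizedExperiment::assay(cm, assay)[gene, cells]),
    treatment = as.numeric(cd$arm == "NAT"),
    subject = factor(cd$subject))
  nsub <- tapply(dat$subject, dat$treatment, function(s) length(unique(s)))
  if (length(nsub) < 2L || any(nsub < 2L))
    stop("need at least two subjects per arm (treatment otherwise ",
         "confounded with subject)", call. = FALSE)
  within_var <- sum(tapply(dat$y, dat$subject,
                           function(v) sum((v - mean(v))^2))) /
    (nrow(dat) - nlevels(dat$subject))
  if (within_var < 1e-10) {
    sm <- tapply(dat$y, dat$subject, mean)
    tr <- tapply(dat$treatment, dat$subject, mean)
    tt <- t.test(sm[tr == 1], sm[tr == 0], var.equal = TRUE)
    est <- unname(diff(rev(tt$estimate)))
    se <- abs(est / tt$statistic)
    if (!is.finite(se)) se <- 0
    p2 <- tt$p.value
    hyp <- if (direction == "greater") est > 0 else est < 0
    return(list(estimate = est, se = se,
                p_one_tailed = if (hyp) p2 / 2 else 1 - p2 / 2,
                p_two_tailed = p2, method = "subject-mean t-test"))
  }
  fit <- lmer(y ~ treatment + (1 | subject), data = dat, REML = TRUE,
              control = lmerControl(check.conv.singular = "ignore"))
  est <- unname(fixef(fit)["treatment"])
  se <- sqrt(stats::vcov(fit)["treatment", "treatment"])
  p <- .oneTailedP(est, se, direction)
  list(estimate = est, se = se, p_one_tailed = p$one, p_two_tailed = p$two,
       method = "linear mixed model (REML, Wald)")
}

#' Binomial mixed-model test of high-expression cell proportions
#'
#' \code{high-expression flag ~ treatment, random = (1 | subject),
#' binomial}; per-cell Bernoulli flags are aggregated to per-subject
#' binomial counts (identical likelihood) and fitted by Laplace
#' approximation. Reports the treatment log-odds, a one-tailed Wald p in
#' the pre-registered direction, and the raw per-arm flagged percentages.
#'
#' @param flags A \code{HighExpressionFlags} object (or named logical
#'   vector over cells).
#' @param cell_meta \code{data.frame} with rownames = cell ids and columns
#'   \code{subject}, \code{arm} (e.g. \code{segmentData} of the
#'   \linkS4class{CellCounts}).
#' @param direction \code{"greater"} (NAT > naive, default) or
#'   \code{"less"}.
#' @return List with estimate (log-odds), se, p_one_tailed, p_two_tailed,
#'   per-arm percentages (\code{pct}), the per-subject table, and a
#'   \code{separation} flag.
#' @export
glmmProportionTest <- function(flags, cell_meta,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (inherits(flags, "HighExpressionFlags")) flags <- flags$flags
  cell_meta <- as.data.frame(cell_meta)
  miss <- setdiff(names(flags), rownames(cell_meta))
  if (length(miss))
    stop("metadata missing for ", length(miss), " flagged cell(s)",
         call. = FALSE)
  cm <- cell_meta[names(flags), , drop = FALSE]
  tab <- stats::aggregate(cbind(x = as.numeric(flags),
                                n = rep(1, length(flags))),
                          by = list(subject = cm$subject, arm = cm$arm),
                          FUN = sum)
  pct <- vapply(.ARMS, function(a)
    100 * sum(tab$x[tab$arm == a]) / sum(tab$n[tab$arm == a]), numeric(1))
  arm_flag_rates <- tapply(as.numeric(flags), cm$arm, mean)
  separation <- any(arm_flag_rates %in% c(0, 1))
  tab$treatment <- as.numeric(tab$arm == "NAT")
  fit <- tryCatch(
    glmer(cbind(x, n - x) ~ treatment + (1 | subject), data = tab,
          family = stats::binomial(),
          control = glmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(estimate = NA_real_, se = NA_real_, p_one_tailed = NA_real_,
                p_two_tailed = NA_real_, pct = pct, table = tab,
                separation = TRUE))
  }
  est <- unname(fixef(fit)["treatment"])
  se <- sqrt(as.matrix(stats::vcov(fit))["treatment", "treatment"])
  p <- .oneTailedP(est, se, direction)
  list(estimate = est, se = se, p_one_tailed = p$one, p_two_tailed = p$two,
       pct = pct, table = tab, separation = separation)
}
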