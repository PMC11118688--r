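# Covariate coding shared by all linear models: age centered in years,
# sex/grade/margin as indicators, stage as an ordered integer.
.codeCovariates <- function(covdf, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, colnames(covdf))
  if (length(miss))
    stop("covariate(s) not available: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- lapply(covariates, function(cv) {
    v <- covdf[[cv]]
    if (cv == "age") return(matrix(as.numeric(v) - mean(as.numeric(v)),
                                   dimnames = list(NULL, "age")))
    if (cv == "stage") {
      if (!is.numeric(v)) v <- as.integer(factor(v, levels = sort(unique(v))))
      return(matrix(as.numeric(v), dimnames = list(NULL, "stage")))
    }
    if (is.numeric(v)) return(matrix(v, dimnames = list(NULL, cv)))
    f <- factor(v)
    if (nlevels(f) < 2L)
      stop("covariate '", cv, "' is constant", call. = FALSE)
    mm <- model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(cv, levels(f)[-1L])
    mm
  })
  do.call(cbind, cols)
}

.checkFullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qrX
}

# OLS of every row of Y (genes x samples) on X; returns the coefficient of
# `term` with its t-based two-sided p. Rows with missing values are refit on
# their complete samples.
.fitRowsOLS <- function(Y, X, term) {
  p <- ncol(X)
  fitOne <- function(y) {
    ok <- is.finite(y)
    n <- sum(ok)
    if (n <= p) return(c(NA_real_, NA_real_, NA_real_))
    Xi <- X[ok, , drop = FALSE]
    f <- lm.fit(Xi, y[ok])
    xtxi <- chol2inv(qr.R(f$qr))
    rss <- sum(f$residuals^2)
    df <- n - p
    est <- f$coefficients[term]
    se <- sqrt(rss / df * xtxi[match(term, colnames(Xi)),
                               match(term, colnames(Xi))])
    if (se == 0) {
      pval <- if (est == 0) 1 else 0
    } else {
      pval <- 2 * pt(-abs(est / se), df)
    }
    c(est, se, pval)
  }
  if (all(is.finite(Y))) {
    qrX <- qr(X)
    n <- nrow(X)
    df <- n - p
    if (df <= 0L)
      stop("no residual degrees of freedom (n = ", n, ", parameters = ", p,
           ")", call. = FALSE)
    coefs <- qr.coef(qrX, t(Y))
    res <- t(Y) - X %*% coefs
    rss <- colSums(res^2)
    xtxi <- chol2inv(qr.R(qrX))
    j <- match(term, colnames(X))
    est <- coefs[j, ]
    se <- sqrt(rss / df * xtxi[j, j])
    tstat <- est / se
    pval <- 2 * pt(-abs(tstat), df)
    pval[se == 0 & est == 0] <- 1
    pval[se == 0 & est != 0] <- 0
    out <- cbind(est, se, pval)
  } else {
    out <- t(apply(Y, 1L, fitOne))
  }
  colnames(out) <- c("estimate", "se", "p_value")
  rownames(out) <- rownames(Y)
  out
}

#' Subject-wise average expression per compartment
#'
#' For each subject, the linear-scale mean of a gene's expression across
#' that subject's segments in the requested compartment, then log2 (values
#' floored before the log). Subjects without a qualifying segment are
#' excluded with a warning.
#'
#' @param em A (normalized) \linkS4class{GeneExpressionSet}.
#' @param seg Segment annotation; defaults to \code{segmentData(em)}.
#' @param compartment \code{"carcinoma"} or \code{"TME"}.
#' @param floor Floor applied before log2 (default 0.5).
#' @return A \linkS4class{SubjectProfile}.
#' @export
subjectAverage <- function(em, seg = segmentData(em),
                           compartment = c("carcinoma", "TME"), floor = 0.5) {
  stopifnot(is(em, "GeneExpressionSet"))
  compartment <- match.arg(compartment)
  seg <- .validateSegmentTable(seg, segment_ids = colnames(em))
  seg <- seg[colnames(em), , drop = FALSE]
  in_comp <- seg$compartment == compartment
  lost <- setdiff(unique(seg$subject_id), unique(seg$subject_id[in_comp]))
  if (length(lost))
    warning("subject(s) without ", compartment, " segments excluded: ",
            paste(lost, collapse = ", "), call. = FALSE)
  if (!any(in_comp))
    stop("no segments in compartment '", compartment, "'", call. = FALSE)
  vals <- assay(em, "exprs")[, in_comp, drop = FALSE]
  subj <- seg$subject_id[in_comp]
  means <- t(rowsum(t(vals), group = subj)) /
    rep(as.vector(table(subj)[sort(unique(subj))]), each = nrow(vals))
  prof <- log2Floor(means, floor)
  covdf <- seg[in_comp, c("subject_id", "arm",
                          intersect(.SUBJECT_COVARIATES, colnames(seg))),
               drop = FALSE]
  covdf <- covdf[!duplicated(covdf$subject_id), , drop = FALSE]
  rownames(covdf) <- covdf$subject_id
  covdf <- covdf[colnames(prof), , drop = FALSE]
  new("SubjectProfile", exprs = prof, covariates = covdf,
      compartment = compartment)
}

#' Covariate-adjusted differential expression between treatment arms
#'
#' Per gene, ordinary least squares of the log2 subject-wise mean
#' expression on a treatment indicator (NAT = 1) plus subject covariates;
#' the treatment coefficient is the log2 effect of therapy and its
#' two-sided p comes from the t distribution. No multiple-testing
#' correction is applied by default (set \code{fdr = TRUE} for a BH column).
#'
#' @param sp A \linkS4class{SubjectProfile}.
#' @param covariates Covariate names to adjust for (default age, sex,
#'   grade, stage).
#' @param fdr Add a Benjamini-Hochberg adjusted column.
#' @return \code{data.frame} with gene, estimate, se, p_value, direction
#'   and volcano-ready \code{neg_log10_p}.
#' @export
fitTreatmentDE <- function(sp, covariates = c("age", "sex", "grade", "stage"),
                           fdr = FALSE) {
  stopifnot(is(sp, "SubjectProfile"))
  covdf <- sp@covariates
  if (length(unique(covdf$arm)) < 2L || min(table(covdf$arm)) < 2L)
    stop("at least two subjects per arm are required", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             treatment = as.numeric(covdf$arm == "NAT"),
             .codeCovariates(covdf, covariates))
  .checkFullRank(X)
  out <- .fitRowsOLS(sp@exprs, X, "treatment")
  res <- data.frame(gene = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$estimate >= 0, "up", "down")
  res$neg_log10_p <- -log10(res$p_value)
  if (fdr) res$fdr <- p.adjust(res$p_value, "BH")
  res
}

#' Compartment marker genes (carcinoma-high vs TME-high)
#'
#' Runs the same linear-model machinery with compartment as the predictor
#' within one treatment arm, on subject-wise compartment averages; genes
#' significant at \code{alpha} are split into carcinoma-high and TME-high
#' lists by the coefficient sign.
#'
#' @param em A (normalized) \linkS4class{GeneExpressionSet}.
#' @param seg Segment annotation; defaults to \code{segmentData(em)}.
#' @param arm \code{"naive"} or \code{"NAT"}.
#' @param alpha Significance threshold on the raw p (default 0.05).
#' @return List with \code{carcinoma_high}, \code{tme_high} and the full
#'   \code{results} table.
#' @export
compartmentMarkers <- function(em, seg = segmentData(em),
                               arm = c("naive", "NAT"), alpha = 0.05) {
  stopifnot(is(em, "GeneExpressionSet"))
  arm <- match.arg(arm)
  seg <- .validateSegmentTable(seg, segment_ids = colnames(em))
  seg <- seg[colnames(em), , drop = FALSE]
  keep <- seg$arm == arm
  if (!any(keep)) stop("no segments in arm '", arm, "'", call. = FALSE)
  emA <- em[, keep]
  segA <- seg[keep, , drop = FALSE]
  profs <- lapply(.COMPARTMENTS, function(cp)
    suppressWarnings(subjectAverage(emA, segA, cp)))
  Y <- do.call(cbind, lapply(profs, function(p) p@exprs))
  compartment <- rep(.COMPARTMENTS,
                     times = vapply(profs, function(p) ncol(p@exprs),
                                    integer(1)))
  X <- cbind(`(Intercept)` = 1,
             carcinoma = as.numeric(compartment == "carcinoma"))
  if (ncol(Y) - ncol(X) <= 0L)
    stop("no residual degrees of freedom: need more than one subject",
         call. = FALSE)
  .checkFullRank(X)
  out <- .fitRowsOLS(Y, X, "carcinoma")
  res <- data.frame(gene = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  sig <- res$p_value < alpha
  list(carcinoma_high = res$gene[sig & res$estimate > 0],
       tme_high = res$gene[sig & res$estimate < 0],
       results = res)
}

#' Highly variable genes by coefficient of variation
#'
#' CV = sd/mean on the normalized linear scale; returns the
#' \code{ceiling(top_fraction * n_genes)} genes with the largest CV, ties
#' broken by gene symbol order. Genes with zero mean are excluded with a
#' warning.
#'
#' @param em A \linkS4class{GeneExpressionSet} with at least 5 genes.
#' @param top_fraction Fraction of genes to keep (default 0.20, the top 20
#'   percentile).
#' @return Character vector of gene symbols.
#' @export
highlyVariableGenes <- function(em, top_fraction = 0.20) {
  stopifnot(is(em, "GeneExpressionSet"))
  if (nrow(em) < 5L) stop("need at least 5 genes", call. = FALSE)
  .assertScalarNumber(top_fraction, "top_fraction")
  vals <- assay(em, "exprs")
  mu <- rowMeans(vals)
  if (any(mu == 0)) {
    warning("excluding gene(s) with zero mean: ",
            paste(rownames(em)[mu == 0], collapse = ", "), call. = FALSE)
  }
  k <- ceiling(top_fraction * nrow(em))
  cv <- apply(vals, 1L, sd) / mu
  cv[mu == 0] <- -Inf
  ord <- order(-cv, rownames(em))
  rownames(em)[ord][seq_len(min(k, sum(is.finite(cv))))]
}
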