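#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Subject-level complement-panel matrix
#'
#' Per subject and panel gene, the mean expression over that subject's TME
#' segments (linear scale). Subjects without a TME segment are excluded
#' with a warning.
#'
#' @param em A (normalized) \linkS4class{GeneExpressionSet}.
#' @param seg Segment annotation; defaults to \code{segmentData(em)}.
#' @param panel Panel genes (default the five-gene complement panel).
#' @param arm Restrict to one treatment arm (default \code{"NAT"}, the arm
#'   the stratification is defined for); \code{NULL} keeps all subjects.
#' @return List with \code{panel_matrix} (subjects x genes) and
#'   \code{mean_score} (row means).
#' @export
complementSubjectScore <- function(em, seg = segmentData(em),
                                   panel = complementPanel(), arm = "NAT") {
  stopifnot(is(em, "GeneExpressionSet"))
  miss <- setdiff(panel, rownames(em))
  if (length(miss))
    stop("panel gene(s) absent from the expression matrix ",
         "(filtered upstream?): ", paste(miss, collapse = ", "),
         call. = FALSE)
  seg <- .validateSegmentTable(seg, segment_ids = colnames(em))
  seg <- seg[colnames(em), , drop = FALSE]
  if (!is.null(arm)) {
    keep <- seg$arm %in% arm
    em <- em[, keep]
    seg <- seg[keep, , drop = FALSE]
  }
  in_tme <- seg$compartment == "TME"
  lost <- setdiff(unique(seg$subject_id), unique(seg$subject_id[in_tme]))
  if (length(lost))
    warning("subject(s) without TME segments excluded: ",
            paste(lost, collapse = ", "), call. = FALSE)
  if (!any(in_tme)) stop("no TME segments", call. = FALSE)
  vals <- assay(em, "exprs")[panel, in_tme, drop = FALSE]
  subj <- seg$subject_id[in_tme]
  pm <- rowsum(t(vals), group = subj) / as.vector(table(subj))
  list(panel_matrix = pm[, panel, drop = FALSE],
       mean_score = rowMeans(pm[, panel, drop = FALSE]))
}

#' Stratify subjects into high/low complement subgroups
#'
#' Unsupervised hierarchical clustering (Ward linkage on Euclidean
#' distances of the log2 panel values by default) cut at k = 2; the
#' cluster with the larger mean panel value is labeled \code{"high"}.
#'
#' @param panel_matrix Subjects x panel-genes matrix of mean TME expression
#'   (from \code{\link{complementSubjectScore}}).
#' @param log2_scale Cluster on log2 values (heatmap convention,
#'   default TRUE).
#' @param linkage \code{hclust} linkage method (default \code{"ward.D2"}).
#' @param floor Floor before log2.
#' @return Object of class \code{SubgroupAssignment}: list with
#'   \code{labels} (named subject -> "high"/"low"), \code{panel_matrix},
#'   and the \code{hclust} tree.
#' @export
stratifyComplement <- function(panel_matrix, log2_scale = TRUE,
                               linkage = "ward.D2", floor = 0.5) {
  pm <- as.matrix(panel_matrix)
  if (nrow(pm) < 4L) stop("need at least 4 subjects to stratify", call. = FALSE)
  X <- if (log2_scale) log2Floor(pm, floor) else pm
  if (all(apply(X, 2L, function(v) diff(range(v)) == 0)))
    stop("degenerate panel: all subjects identical", call. = FALSE)
  hc <- hclust(dist(X), method = linkage)
  cl <- cutree(hc, k = 2L)
  high_id <- as.integer(names(which.max(tapply(rowMeans(X), cl, mean))))
  labels <- setNames(ifelse(cl == high_id, "high", "low"), rownames(pm))
  structure(list(labels = labels, panel_matrix = pm, tree = hc),
            class = "SubgroupAssignment")
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group and the log-rank chi-square
#' (k - 1 degrees of freedom for k groups).
#'
#' @param surv Survival table (\code{subject_id}, \code{time_months},
#'   \code{event}).
#' @param groups Named vector, subject id -> group label.
#' @return List with the \code{survfit} object, \code{chisq}, \code{df}
#'   and \code{p}.
#' @export
kmLogrank <- function(surv, groups) {
  surv <- .validateSurvivalTable(surv)
  labs <- groups[surv$subject_id]
  if (any(is.na(labs)))
    stop("group label missing for subject(s): ",
         paste(surv$subject_id[is.na(labs)], collapse = ", "), call. = FALSE)
  tab <- table(labs)
  if (length(tab) < 2L || any(tab == 0))
    stop("each group needs at least one subject", call. = FALSE)
  group <- factor(labs)
  fit <- survfit(Surv(surv$time_months, surv$event) ~ group)
  if (sum(surv$event) == 0)
    return(list(fit = fit, chisq = 0, df = length(tab) - 1L, p = 1))
  sd <- survdiff(Surv(surv$time_months, surv$event) ~ group)
  df <- length(tab) - 1L
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood maximization with Efron tie handling; Wald 95\% CI
#' and p per covariate. Monotone likelihood (perfect separation) is
#' flagged and the affected CI reported as unbounded.
#'
#' @param surv Survival table with covariate columns (a \code{subgroup}
#'   column may be added from \code{\link{stratifyComplement}} labels).
#' @param covariates Covariate column names (default the forest-plot set:
#'   subgroup, age, sex, tumor_size, grade, margin).
#' @return List of class \code{CoxResult}: \code{table} (term, hr, lo, hi,
#'   p, flagged), \code{loglik}, and the fitted model.
#' @export
coxPH <- function(surv, covariates = c("subgroup", "age", "sex",
                                       "tumor_size", "grade", "margin")) {
  surv <- .validateSurvivalTable(surv)
  miss <- setdiff(covariates, colnames(surv))
  if (length(miss))
    stop("covariate(s) not in the survival table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cv in covariates)
    if (length(unique(surv[[cv]])) < 2L)
      stop("covariate '", cv, "' is constant", call. = FALSE)
  if (sum(surv$event) < length(covariates) + 1L)
    warning("fewer events (", sum(surv$event), ") than covariates + 1; ",
            "estimates will be unstable", call. = FALSE)
  dat <- surv[, c("time_months", "event", covariates), drop = FALSE]
  dat$subgroup <- if ("subgroup" %in% covariates)
    factor(dat$subgroup, levels = c("low", "high")) else NULL
  fml <- stats::as.formula(paste("Surv(time_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- coxph(fml, data = dat, ties = "efron")
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  flagged <- !is.finite(beta) | !is.finite(se) | abs(beta) > 10 | se > 100
  lo <- exp(beta - qnorm(0.975) * se)
  hi <- exp(beta + qnorm(0.975) * se)
  lo[flagged] <- 0
  hi[flagged] <- Inf
  tab <- data.frame(term = names(beta), hr = exp(beta), lo = lo, hi = hi,
                    p = 2 * pnorm(-abs(beta / se)), flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(flagged))
    warning("monotone likelihood suspected for: ",
            paste(tab$term[flagged], collapse = ", "), call. = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L], model = fit),
            class = "CoxResult")
}

#' Paired pre/post treatment change in TME expression of one gene
#'
#' For subjects with both a pre-treatment biopsy and a post-treatment
#' resection, the change is the mean post log2 expression minus the mean
#' pre log2 expression across TME segments; when both sides have at least
#' two segments, a one-sided Welch test (post > pre) classifies the
#' subject as \code{"increased"} at \code{alpha}. With a single segment on
#' either side the delta is reported but the test is skipped with a
#' warning.
#'
#' @param em A (normalized) \linkS4class{GeneExpressionSet}.
#' @param seg Segment annotation; defaults to \code{segmentData(em)}.
#' @param pairs Named list, subject id -> \code{list(pre = segment ids,
#'   post = segment ids)}.
#' @param gene Gene to test (default \code{"C3"}).
#' @param alpha Significance level (default 0.05).
#' @param floor Floor before log2.
#' @return \code{data.frame} with subject, delta, p_value and
#'   classification (\code{"increased"}, \code{"not-increased"}, or NA when
#'   untested).
#' @export
pairedPrePostDelta <- function(em, seg = segmentData(em), pairs,
                               gene = "C3", alpha = 0.05, floor = 0.5) {
  stopifnot(is(em, "GeneExpressionSet"))
  if (!gene %in% rownames(em))
    stop("gene '", gene, "' not in the expression matrix", call. = FALSE)
  vals <- log2Floor(assay(em, "exprs")[gene, ], floor)
  rows <- lapply(names(pairs), function(sj) {
    pr <- pairs[[sj]]
    if (is.null(pr$pre) || is.null(pr$post) ||
        !length(pr$pre) || !length(pr$post) ||
        !all(c(pr$pre, pr$post) %in% names(vals))) {
      warning("pair for subject '", sj, "' is incomplete; skipped",
              call. = FALSE)
      return(NULL)
    }
    pre <- vals[pr$pre]; post <- vals[pr$post]
    delta <- mean(post) - mean(pre)
    if (length(pre) >= 2L && length(post) >= 2L &&
        (sd(pre) > 0 || sd(post) > 0)) {
      p <- t.test(post, pre, alternative = "greater")$p.value
      cls <- if (delta > 0 && p < alpha) "increased" else "not-increased"
    } else {
      if (length(pre) < 2L || length(post) < 2L)
        warning("subject '", sj, "': single segment on one side; ",
                "test skipped", call. = FALSE)
      p <- NA_real_
      cls <- if (delta == 0) "not-increased" else NA_character_
    }
    data.frame(subject = sj, delta = delta, p_value = p,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = character(0), delta = numeric(0),
                      p_value = numeric(0), classification = character(0))
  rownames(out) <- NULL
  out
}

#' @export
print.SubgroupAssignment <- function(x, ...) {
  cat(sprintf("SubgroupAssignment: %d high / %d low of %d subjects\n",
              sum(x$labels == "high"), sum(x$labels == "low"),
              length(x$labels)))
  invisible(x)
}

#' @export
print.CoxResult <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties), log-likelihood ",
      sprintf("%.3f", x$loglik), "\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}
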