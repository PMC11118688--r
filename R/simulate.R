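#' Configuration for the spatial cohort simulator
#'
#' Defaults emulate the study design the pipeline targets: 13 naive and 23
#' NAT-treated subjects, 2-5 ROIs each split into a carcinoma and a TME
#' segment, an 1,800-gene panel with 100 negative-control probes,
#' negative-binomial counts with log-normal gene baselines and segment size
#' factors, symmetric compartment markers, a 2-fold upregulation of the
#' five-gene complement panel in every treated TME segment with a further
#' 2-fold elevation in treated "responder" subjects (a fixed 40\% of the
#' treated arm, the high-complement subgroup), exponential survival with a
#' responder hazard ratio of 0.2 and 30\% censoring, and a planted 6\%
#' segment QC failure rate.
#'
#' @param seed Integer RNG seed (mandatory; full determinism).
#' @param n_subjects Named vector, subjects per arm.
#' @param rois_range Min/max ROIs per subject.
#' @param n_genes Panel size (incl. complement and marker genes).
#' @param probes_per_gene Probes per gene (collapsed by geometric mean).
#' @param n_negative_probes Negative-control probes.
#' @param baseline_log_mean,baseline_log_sd Log-normal gene-baseline
#'   parameters (natural log of counts).
#' @param complement_baseline Fixed baseline count of the panel genes.
#' @param nb_size Negative-binomial size (1/dispersion).
#' @param n_compartment_markers Markers planted per compartment.
#' @param compartment_marker_fold Fold change of compartment markers.
#' @param complement_genes The stratification panel.
#' @param complement_fold Fold applied in all treated TME segments;
#'   responder subjects carry it twice (a \code{complement_fold^2} total),
#'   so \code{complement_fold = 1} is a complete null.
#' @param responder_fraction Fraction of treated subjects that respond
#'   (realized as a fixed count).
#' @param subject_log_sd,segment_log_sd Log-normal random-effect SDs.
#' @param neg_mean Mean negative-probe count.
#' @param qc_fail_fraction Fraction of segments planted to fail segment QC.
#' @param surv_base_rate Baseline exponential hazard (per month).
#' @param surv_hr True hazard ratio, responder vs non-responder.
#' @param censoring Expected censoring fraction.
#' @return Validated list of class \code{SpatialSimConfig}.
#' @export
spatialSimConfig <- function(seed,
                             n_subjects = c(naive = 13, NAT = 23),
                             rois_range = c(2, 5),
                             n_genes = 1800,
                             probes_per_gene = 1,
                             n_negative_probes = 100,
                             baseline_log_mean = 3,
                             baseline_log_sd = 1.1,
                             complement_baseline = 40,
                             nb_size = 10,
                             n_compartment_markers = 80,
                             compartment_marker_fold = 4,
                             complement_genes = complementPanel(),
                             complement_fold = 2,
                             responder_fraction = 0.4,
                             subject_log_sd = 0.1,
                             segment_log_sd = 0.3,
                             neg_mean = 3,
                             qc_fail_fraction = 0.06,
                             surv_base_rate = log(2) / 24,
                             surv_hr = 0.2,
                             censoring = 0.3) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  for (nm in c("complement_fold", "compartment_marker_fold", "surv_hr",
               "surv_base_rate", "nb_size", "neg_mean"))
    .assertScalarNumber(cfg[[nm]], nm)
  for (nm in c("responder_fraction", "censoring", "qc_fail_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  if (cfg$n_genes < length(cfg$complement_genes) +
      2 * cfg$n_compartment_markers)
    stop("infeasible config: more marker/panel genes than genes",
         call. = FALSE)
  structure(cfg, class = "SpatialSimConfig")
}

#' Simulate a segmented spatial transcriptomics cohort
#'
#' Generates probe-level counts, segment annotation and subject survival
#' with every planted effect recorded in a truth manifest. The same seed
#' always reproduces identical outputs.
#'
#' @param cfg A \code{\link{spatialSimConfig}}.
#' @return List with \code{probes} (\linkS4class{ProbeCountSet} incl.
#'   segment annotation), \code{segments} (annotation \code{data.frame}),
#'   \code{survival} (subject table) and \code{truth} (manifest of planted
#'   effects, serializable as JSON).
#' @export
generateSpatial <- function(cfg) {
  stopifnot(inherits(cfg, "SpatialSimConfig"))
  set.seed(cfg$seed)
  arms <- rep(names(cfg$n_subjects), cfg$n_subjects)
  n_subj <- length(arms)
  subjects <- sprintf("P%02d", seq_len(n_subj))
  covdf <- data.frame(
    subject_id = subjects, arm = arms,
    age = round(rnorm(n_subj, 65, 8)),
    sex = sample(c("M", "F"), n_subj, replace = TRUE),
    grade = sample(c("G1", "G2", "G3"), n_subj, replace = TRUE,
                   prob = c(0.2, 0.5, 0.3)),
    stage = sample(1:3, n_subj, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    tumor_size = round(rlnorm(n_subj, log(3), 0.3), 1),
    margin = sample(c("R0", "R1"), n_subj, replace = TRUE,
                    prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
  nat_ids <- subjects[arms == "NAT"]
  responders <- sort(sample(nat_ids,
                            round(cfg$responder_fraction * length(nat_ids))))

  n_rois <- sample(cfg$rois_range[1L]:cfg$rois_range[2L], n_subj,
                   replace = TRUE)
  seg <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    expand.grid(roi = seq_len(n_rois[i]), compartment = .COMPARTMENTS,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE) |>
      transform(subject_id = subjects[i])
  }))
  seg$roi_id <- paste0(seg$subject_id, "_R", seg$roi)
  seg$segment_id <- paste0(seg$roi_id, "_", seg$compartment)
  seg <- seg[order(seg$segment_id), ]
  n_seg <- nrow(seg)
  seg <- cbind(seg[c("segment_id", "roi_id", "subject_id", "compartment")],
               covdf[match(seg$subject_id, covdf$subject_id),
                     c("arm", .SUBJECT_COVARIATES)])
  seg$raw_reads <- round(rlnorm(n_seg, log(2e5), 0.3))
  seg$aligned_pct <- round(runif(n_seg, 85, 99.9), 2)
  seg$trimmed_pct <- round(runif(n_seg, 85, 99.9), 2)
  seg$stitched_pct <- round(runif(n_seg, 85, 99.9), 2)
  rownames(seg) <- seg$segment_id

  # planted QC failures, never exhausting a subject's compartment coverage
  n_fail <- round(cfg$qc_fail_fraction * n_seg)
  comp_key <- paste(seg$subject_id, seg$compartment)
  eligible <- seg$segment_id[comp_key %in%
                               names(which(table(comp_key) >= 2))]
  planted <- data.frame(segment_id = character(0), reason = character(0))
  taken_keys <- character(0)
  for (sid in sample(eligible)) {
    if (nrow(planted) >= n_fail) break
    key <- comp_key[match(sid, seg$segment_id)]
    if (sum(taken_keys == key) >= sum(comp_key == key) - 1L) next
    taken_keys <- c(taken_keys, key)
    reason <- if (nrow(planted) %% 2 == 0) "raw_reads" else "aligned_pct"
    if (reason == "raw_reads")
      seg[sid, "raw_reads"] <- round(runif(1, 200, 999))
    else
      seg[sid, "aligned_pct"] <- round(runif(1, 60, 79.5), 2)
    planted <- rbind(planted, data.frame(segment_id = sid, reason = reason))
  }

  # gene panel: complement + symmetric compartment markers + fillers
  carc_markers <- sprintf("CARC%03d", seq_len(cfg$n_compartment_markers))
  tme_markers <- sprintf("TMEM%03d", seq_len(cfg$n_compartment_markers))
  n_fill <- cfg$n_genes - length(cfg$complement_genes) -
    2L * cfg$n_compartment_markers
  genes <- c(cfg$complement_genes, carc_markers, tme_markers,
             sprintf("GENE%04d", seq_len(n_fill)))
  base <- rlnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(base) <- genes
  base[cfg$complement_genes] <- cfg$complement_baseline

  subj_eff <- setNames(rlnorm(n_subj, 0, cfg$subject_log_sd), subjects)
  seg_fac <- rlnorm(n_seg, 0, cfg$segment_log_sd)
  lmu <- outer(log(base), log(seg_fac * subj_eff[seg$subject_id]), "+")
  colnames(lmu) <- seg$segment_id
  is_carc <- seg$compartment == "carcinoma"
  lmu[carc_markers, is_carc] <- lmu[carc_markers, is_carc] +
    log(cfg$compartment_marker_fold)
  lmu[tme_markers, !is_carc] <- lmu[tme_markers, !is_carc] +
    log(cfg$compartment_marker_fold)
  arm_tme <- seg$compartment == "TME" & seg$arm == "NAT"
  lmu[cfg$complement_genes, arm_tme] <- lmu[cfg$complement_genes, arm_tme] +
    log(cfg$complement_fold)
  boost <- seg$compartment == "TME" & seg$subject_id %in% responders
  lmu[cfg$complement_genes, boost] <- lmu[cfg$complement_genes, boost] +
    log(cfg$complement_fold)

  probe_gene <- rep(genes, each = cfg$probes_per_gene)
  probe_ids <- if (cfg$probes_per_gene == 1L) probe_gene
  else paste0(probe_gene, "_p",
              rep(seq_len(cfg$probes_per_gene), times = cfg$n_genes))
  mu <- exp(lmu)[probe_gene, , drop = FALSE]
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = cfg$nb_size),
                   nrow = nrow(mu),
                   dimnames = list(probe_ids, seg$segment_id))
  neg_ids <- sprintf("NegProbe%03d", seq_len(cfg$n_negative_probes))
  neg_mu <- outer(rep(cfg$neg_mean, cfg$n_negative_probes), seg_fac)
  negs <- matrix(rnbinom(length(neg_mu), mu = as.vector(neg_mu),
                         size = cfg$nb_size),
                 nrow = cfg$n_negative_probes,
                 dimnames = list(neg_ids, seg$segment_id))
  pcm <- ProbeCountSet(rbind(counts, negs),
                       gene = c(probe_gene, neg_ids),
                       negative = c(rep(FALSE, length(probe_ids)),
                                    rep(TRUE, cfg$n_negative_probes)),
                       segmentData = seg)

  is_resp <- covdf$subject_id %in% responders
  rate <- cfg$surv_base_rate * ifelse(is_resp, cfg$surv_hr, 1)
  t_event <- rexp(n_subj, rate)
  t_cens <- if (cfg$censoring > 0)
    rexp(n_subj, rate * cfg$censoring / (1 - cfg$censoring))
  else rep(Inf, n_subj)
  survival <- data.frame(
    subject_id = subjects,
    time_months = pmax(round(pmin(t_event, t_cens), 2), 0.01),
    event = as.integer(t_event <= t_cens),
    covdf[, c("arm", .SUBJECT_COVARIATES)],
    stringsAsFactors = FALSE, row.names = subjects)

  truth <- list(seed = cfg$seed,
                responders = responders,
                complement_genes = cfg$complement_genes,
                complement_fold = cfg$complement_fold,
                carcinoma_markers = carc_markers,
                tme_markers = tme_markers,
                compartment_marker_fold = cfg$compartment_marker_fold,
                planted_qc_failures = planted,
                true_hr = cfg$surv_hr,
                censoring = cfg$censoring)
  list(probes = pcm, segments = seg, survival = survival, truth = truth)
}

#' Configuration for the single-nucleus cohort simulator
#'
#' Defaults emulate the validation cohort at reduced scale: 15 naive and 11
#' treated subjects, 350 cells per subject across CAF / tumor / immune /
#' endothelial types, four CAF subtypes with planted 3-fold 25-gene
#' signatures, and C3 values constructed so the non-zero-median high-cell
#' rule recovers per-arm target proportions of 5\% (naive) and 10\%
#' (treated) among CAFs.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_subjects Named vector, subjects per arm.
#' @param cells_per_subject Cells per subject: a single number or a named
#'   per-arm vector (e.g. \code{c(naive = 5869, NAT = 4592)}).
#' @param n_genes Gene count (incl. C3 and signature genes).
#' @param cell_type_props Cell-type mixture (sums to 1).
#' @param caf_subtype_props CAF subtype mixture (sums to 1).
#' @param signature_size Genes per subtype signature.
#' @param signature_fold Fold change of a subtype's signature genes in its
#'   cells.
#' @param signature_baseline Median baseline count of signature genes
#'   (drawn log-normally around it).
#' @param c3_high_target Named per-arm target C3-high proportions among
#'   CAFs (must be below 0.5 to be compatible with the pooled-median rule).
#' @param c3_subject_sd Subject-level SD on the logit of the high
#'   probability.
#' @param baseline_log_mean,baseline_log_sd Log-normal gene baselines.
#' @param lib_log_sd Log-normal cell library-size factor SD.
#' @param nb_size Negative-binomial size.
#' @param dropout Extra zero-inflation rate (not applied to the planted C3
#'   values, whose zero pattern is explicit).
#' @return Validated list of class \code{CellSimConfig}.
#' @export
cellSimConfig <- function(seed,
                          n_subjects = c(naive = 15, NAT = 11),
                          cells_per_subject = 350,
                          n_genes = 400,
                          cell_type_props = c(CAF = 0.4, tumor = 0.3,
                                              immune = 0.2,
                                              endothelial = 0.1),
                          caf_subtype_props = c(myofibroblastic = 0.35,
                                                adhesive = 0.25,
                                                immunomodulatory = 0.22,
                                                neurotrophic = 0.18),
                          signature_size = 25,
                          signature_fold = 3,
                          signature_baseline = 2,
                          c3_high_target = c(naive = 0.05, NAT = 0.10),
                          c3_subject_sd = 0.2,
                          baseline_log_mean = log(0.5),
                          baseline_log_sd = 1.2,
                          lib_log_sd = 0.2,
                          nb_size = 2,
                          dropout = 0.3) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  if (abs(sum(cfg$cell_type_props) - 1) > 1e-8)
    stop("cell_type_props must sum to 1", call. = FALSE)
  if (abs(sum(cfg$caf_subtype_props) - 1) > 1e-8)
    stop("caf_subtype_props must sum to 1", call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (any(cfg$c3_high_target <= 0) || any(cfg$c3_high_target >= 0.5))
    stop("target proportions incompatible with the pooled-median rule ",
         "(must lie in (0, 0.5))", call. = FALSE)
  if (cfg$n_genes < 1L + cfg$signature_size *
      length(cfg$caf_subtype_props) + cfg$signature_size)
    stop("infeasible config: not enough genes for the signatures",
         call. = FALSE)
  structure(cfg, class = "CellSimConfig")
}

#' Simulate a sparse single-nucleus validation cohort
#'
#' Negative-binomial counts with dropout, planted CAF-subtype signatures,
#' and C3 values constructed so that the pooled non-zero-median rule
#' recovers the per-arm target high-cell proportions in expectation. A
#' per-cell truth manifest records every planted label.
#'
#' @param cfg A \code{\link{cellSimConfig}}.
#' @return List with \code{cells} (a \linkS4class{CellCounts}),
#'   \code{signatures} (the planted subtype signatures) and \code{truth}
#'   (per-cell manifest plus planted parameters).
#' @export
generateCells <- function(cfg) {
  stopifnot(inherits(cfg, "CellSimConfig"))
  set.seed(cfg$seed)
  arms <- rep(names(cfg$n_subjects), cfg$n_subjects)
  subjects <- sprintf("D%02d", seq_along(arms))
  cps <- cfg$cells_per_subject
  n_per_subj <- if (length(cps) == 1L) rep(cps, length(arms))
                else unname(cps[arms])
  n_cells <- sum(n_per_subj)
  cell_subject <- rep(subjects, times = n_per_subj)
  cell_arm <- rep(arms, times = n_per_subj)
  cell_type <- sample(names(cfg$cell_type_props), n_cells, replace = TRUE,
                      prob = cfg$cell_type_props)
  subtype <- rep(NA_character_, n_cells)
  is_caf <- cell_type == "CAF"
  subtype[is_caf] <- sample(names(cfg$caf_subtype_props), sum(is_caf),
                            replace = TRUE, prob = cfg$caf_subtype_props)
  cell_ids <- sprintf("%s_c%04d", cell_subject,
                      stats::ave(seq_len(n_cells), cell_subject,
                                 FUN = seq_along))

  sub_names <- names(cfg$caf_subtype_props)
  sig_genes <- lapply(seq_along(sub_names), function(i)
    sprintf("%s%03d", toupper(substr(sub_names[i], 1, 3)),
            seq_len(cfg$signature_size)))
  names(sig_genes) <- sub_names
  n_fill <- cfg$n_genes - 1L - cfg$signature_size * length(sub_names)
  genes <- c("C3", unlist(sig_genes, use.names = FALSE),
             sprintf("GENE%04d", seq_len(n_fill)))
  base <- rlnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(base) <- genes
  # signature genes occupy a mid-expression band so rank-matched background
  # genes exist on both sides
  base[unlist(sig_genes)] <- rlnorm(cfg$signature_size * length(sub_names),
                                    log(cfg$signature_baseline), 0.5)

  lib <- rlnorm(n_cells, 0, cfg$lib_log_sd)
  mu <- outer(base, lib)
  for (st in sub_names) {
    idx <- which(is_caf & subtype == st)
    mu[sig_genes[[st]], idx] <- mu[sig_genes[[st]], idx] * cfg$signature_fold
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = cfg$nb_size),
                   nrow = cfg$n_genes, dimnames = list(genes, cell_ids))
  if (cfg$dropout > 0) {
    keep <- matrix(runif(length(counts)) >= cfg$dropout, nrow = nrow(counts))
    counts <- counts * keep
  }

  # planted C3 structure among CAFs: high cells sit strictly above the
  # non-zero low-expressor band so the pooled non-zero median lands in the
  # gap between them
  target <- cfg$c3_high_target[cell_arm]
  subj_shift <- setNames(rnorm(length(subjects), 0, cfg$c3_subject_sd),
                         subjects)
  p_high <- stats::plogis(stats::qlogis(target) + subj_shift[cell_subject])
  c3_high <- is_caf & runif(n_cells) < p_high
  n_caf <- sum(is_caf)
  h_exp <- sum(cfg$c3_high_target[cell_arm[is_caf]])
  r_low <- min(h_exp / max(n_caf - h_exp, 1), 0.99)
  c3 <- numeric(n_cells)
  c3[c3_high] <- pmax(round(rlnorm(sum(c3_high), log(32), 0.3)), 12)
  low_caf <- is_caf & !c3_high
  low_nz <- low_caf & runif(n_cells) < r_low
  c3[low_nz] <- sample(1:3, sum(low_nz), replace = TRUE,
                       prob = c(0.5, 0.3, 0.2))
  other_nz <- !is_caf & runif(n_cells) < 0.1
  c3[other_nz] <- sample(1:3, sum(other_nz), replace = TRUE)
  counts["C3", ] <- c3

  cells <- CellCounts(
    Matrix::Matrix(counts, sparse = TRUE),
    cellData = data.frame(subject = cell_subject, arm = cell_arm,
                          cell_type = cell_type, subtype = subtype,
                          row.names = cell_ids, stringsAsFactors = FALSE))
  signatures <- lapply(sub_names, function(st)
    GeneSignature(st, sig_genes[[st]]))
  names(signatures) <- sub_names
  truth <- list(seed = cfg$seed,
                cell_manifest = data.frame(
                  cell_id = cell_ids, subject = cell_subject,
                  arm = cell_arm, cell_type = cell_type, subtype = subtype,
                  c3_high = c3_high, stringsAsFactors = FALSE),
                c3_high_target = cfg$c3_high_target,
                signature_fold = cfg$signature_fold,
                signature_genes = sig_genes)
  list(cells = cells, signatures = signatures, truth = truth)
}

#' Simulate subject-level panel scores and survival for the stratification
#' chain
#'
#' A lightweight subject-level generator for the stratify -> log-rank ->
#' Cox chain: responders (a fixed fraction of subjects) carry a
#' \code{panel_fold} shift of the five-gene panel, and survival follows an
#' exponential proportional-hazards model with the given responder hazard
#' ratio and censoring fraction.
#'
#' @param seed Integer RNG seed.
#' @param n Number of subjects.
#' @param responder_fraction Fraction of subjects that are high-panel
#'   responders (fixed count).
#' @param hr True hazard ratio, responder vs non-responder.
#' @param censoring Expected censoring fraction.
#' @param panel_fold Fold shift of panel genes in responders.
#' @param panel_noise_sd SD of log2 panel noise.
#' @param panel_baseline Baseline panel expression.
#' @param base_rate Baseline exponential hazard (per month).
#' @return List with \code{panel_matrix} (n x 5), \code{survival} and
#'   \code{truth} (responder ids).
#' @export
simulateSurvivalCohort <- function(seed, n = 60, responder_fraction = 0.4,
                                   hr = 0.2, censoring = 0.3,
                                   panel_fold = 2, panel_noise_sd = 0.15,
                                   panel_baseline = 40,
                                   base_rate = log(2) / 24) {
  set.seed(seed)
  subjects <- sprintf("S%03d", seq_len(n))
  responders <- sort(sample(subjects, round(responder_fraction * n)))
  is_resp <- subjects %in% responders
  panel <- matrix(
    panel_baseline *
      2 ^ (rnorm(n * 5, 0, panel_noise_sd) +
             log2(panel_fold) * rep(as.numeric(is_resp), 5)),
    nrow = n, dimnames = list(subjects, complementPanel()))
  rate <- base_rate * ifelse(is_resp, hr, 1)
  t_event <- rexp(n, rate)
  t_cens <- if (censoring > 0)
    rexp(n, rate * censoring / (1 - censoring)) else rep(Inf, n)
  survival <- data.frame(
    subject_id = subjects,
    time_months = pmax(pmin(t_event, t_cens), 0.01),
    event = as.integer(t_event <= t_cens),
    age = round(rnorm(n, 65, 8)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    grade = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    tumor_size = round(rlnorm(n, log(3), 0.3), 1),
    margin = sample(c("R0", "R1"), n, replace = TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE, row.names = subjects)
  list(panel_matrix = panel, survival = survival,
       truth = list(responders = responders, hr = hr))
}
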