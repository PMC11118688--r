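---
title: "Methods: segmented DSP analysis of treatment-induced complement remodeling"
author: "SpatialComplement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented DSP analysis of treatment-induced complement remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## The analysis problem

Segmented digital spatial profiling assays (GeoMx DSP-style) measure a
targeted panel of ~1,800 genes in paired compartments of each tissue
region: a carcinoma segment (pan-CK+) and a tumor-microenvironment segment
(SMA+). The scientific questions the pipeline answers are (i) which genes
neoadjuvant therapy (NAT) shifts in each compartment, (ii) whether the
five complement genes C3, C1S, C1R, C4B and C7 stratify treated patients
into prognostically distinct high/low subgroups, and (iii) whether
single-nucleus RNA-seq of an independent cohort confirms that
cancer-associated fibroblasts (CAFs) carry the complement signal.

## QC and normalization

*Segment QC.* A segment passes when `raw_reads >= 1000` and each of the
aligned/trimmed/stitched rates is `>= 80%`. Both thresholds are config
keys (`qcThresholds()`). The read rule is deliberately "at least 1,000":
sequencing workflows universally discard *under*-sequenced segments, and
the package treats the occasionally seen inverted phrasing of this rule as
a typo rather than a method.

*Probe handling.* Multi-probe genes collapse by the geometric mean of
probe counts floored at 0.5. The floor (a config key) avoids `log(0)`
while preserving ordering; it is applied before every geometric mean and
log2 transform in the package. An optional probe-QC step
(`probeQC()`, off by default for single-probe panels) drops a probe whose
across-segment geometric mean falls below 10% of its gene's probe average
— a deliberately simple surrogate for vendor outlier tests, documented as
an interpretation.

*Limit of quantification.* `LOQ(s) = max(2, GM_neg(s) * GSD_neg(s)^2)`,
with the exponent (2) and floor (2) as config keys. Degenerate segments
(fewer than two negative probes, or zero log-variance) fall back to the
floor via GSD = 1 rather than erroring.

*Detection filtering.* Detection is strict (`value > LOQ`). Segments
below 1% gene detection are removed before gene filtering, so a failed
segment cannot drag genes below the 5% rule. The filter is idempotent in
practice because retained genes are exactly those commonly detected in
retained segments.

*Q3 normalization.* Each segment is divided by `Q3(s)/GM(Q3)`. Dividing by
a factor normalized to the geometric mean (rather than by `Q3` itself)
keeps the output on the input's scale — every post-normalization Q3 equals
the geometric mean of the original Q3s — and makes the operation exactly
idempotent on its own output.

## Differential expression

Segments are first averaged to the subject level *on the linear scale*,
then log2-transformed (mean-before-log; the reverse order would estimate a
different, geometric, quantity). Each gene is fit by OLS:

    log2(subject mean) ~ treatment + age + sex + grade + stage

Age is centered; sex, grade and margin are indicator-coded; stage enters
as an ordered integer — the smallest-assumption encodings, since no coding
convention is part of the method. Two-sided p-values use the t
distribution on the residual degrees of freedom. Following common DSP
practice the default significance rule is raw `p < 0.05`; BH-FDR is
available (`fdr = TRUE`) but off by default. Compartment markers reuse the
same machinery with compartment as the predictor within one arm.
Highly-variable-gene selection ranks by CV (sd/mean on the normalized
linear scale) and keeps the top 20th percentile, ties broken by gene
symbol so the selection is deterministic.

## Signature scores and over-representation

A signature score is the geometric mean of the floored expression of the
signature genes present; at least half the signature must be present
(`min_present = 0.5`), and provenance records what was missing. Scores
over marker sets are reported as *signature scores*, never as cell
fractions — the package deliberately does not implement expression
deconvolution, and marker-set fixtures shipped for examples are synthetic
placeholders a user must replace for biological use.

Over-representation uses the hypergeometric upper tail with the EASE
modification (overlap reduced by one) by default, against a universe that
defaults to the genes surviving the detection filter — the panel, not the
genome, is the sampled space. Web-service enrichment portals cannot be
reproduced bit-exactly (server-side annotation versions); this in-package
surrogate accepts any GMT gene sets and documents that its FDR values will
differ from portal output.

## Stratification and survival

Subject-level panel scores are the per-subject means of TME-segment
expression of the five panel genes. Clustering uses Ward linkage
(`ward.D2`) on Euclidean distances of log2 values: Ward is markedly more
stable than complete linkage at n ≈ 23, and log2 matches the heatmap
convention under which such subgroups are read; both are config keys, and
a score-threshold mode is available for users who prefer cutting on the
mean panel score rather than the dendrogram. The "high" label is assigned
by mean panel value, never by cluster index, so the labeling is invariant
to permutations and sign conventions.

Survival uses the product-limit estimator with the log-rank test (the
all-censored edge case returns a zero statistic rather than an error) and
a multivariate Cox model with Efron tie handling — the standard
small-sample-robust default; the covariate set (subgroup, age, sex, tumor
size, grade, margin) is a config key. Monotone likelihood (perfect
separation) is flagged and the affected confidence interval reported as
unbounded rather than as a misleading finite interval.

The paired pre/post comparison reports, per subject, the difference of
mean log2 TME expression of one gene (default C3) between the
post-treatment resection and the pre-treatment biopsy, and classifies a
subject as "increased" when the delta is positive and a one-sided Welch
test across segments clears 0.05. With a single segment on either side the
delta is still reported but the classification is withheld.

## Single-nucleus validation

Counts are library-size normalized to 10,000 per cell and transformed as
`log2(1 + x)` (a config key; the pipeline also accepts pre-normalized
matrices). Subtype assignment compares a cell's signature score (mean of
log2 expression of subtype signature genes) to a *background* score over a
rank-matched gene set: for each signature gene, the candidate whose
across-cell mean-expression rank is nearest, ties resolved to the lower
rank, chosen without replacement. Candidates exclude the signature genes
of *all* subtypes, preventing leakage between programs. A cell may carry
several labels (the rule is per-subtype independent); a single-label
argmax mode exists for reporting.

C3-high cells are those strictly above the median of non-zero C3 values in
the pooled evaluation population. Pooling the arms is deliberate: per-arm
cutoffs would make the per-arm percentages incomparable.

Expression contrasts use `log2(GE) ~ treatment + (1|subject)` fit by REML;
when the within-subject variance vanishes the model degenerates to a
pooled t-test on subject means, which the package detects and reports
explicitly. Proportion contrasts use a binomial GLMM with a subject random
intercept, fit by Laplace approximation after aggregating per-cell
Bernoulli flags to per-subject binomial counts — an identical likelihood
at a fraction of the cost. One-tailed p-values implement the
pre-registered directional hypotheses (complement up in treated
fibroblasts): half the two-tailed Wald p when the estimate has the
hypothesized sign, otherwise one minus half.

## The synthetic cohorts

`generateSpatial()` emulates the targeted-panel study design: 13 naive and
23 treated subjects; 2–5 ROIs per subject, each split into a carcinoma and
a TME segment; 1,800 genes (five complement genes, 80 markers per
compartment at 4-fold, the rest fillers) plus 100 negative-control probes;
negative-binomial counts (size 10) with log-normal gene baselines
(meanlog 3, sdlog 1.1), subject effects (sdlog 0.1) and segment size
factors (sdlog 0.3); negative probes at mean 3. Six percent of segments
are planted to fail segment QC (half low reads, half low aligned rate),
mirroring the roughly one-in-sixteen failure rate typical of such cohorts,
and failures never exhaust a subject's compartment coverage.

The complement panel is induced 2-fold in *every* treated TME segment, and
a fixed 40% of treated subjects ("responders", the high-complement
subgroup) carry the fold a second time. This one-knob design reproduces
the full observed structure — an arm-level TME induction recoverable by
differential expression, a within-arm high/low subgroup recoverable by
clustering, and a survival contrast (exponential proportional hazards,
responder hazard ratio 0.2, 30% censoring) recoverable by log-rank and
Cox — while `complement_fold = 1` with `surv_hr = 1` collapses to a
complete null. Setting `responder_fraction = 0.4` as a fixed count (9 of
23) rather than a Bernoulli draw reflects how a realized cohort presents
itself and keeps the planted subgroup size constant across seeds.

`generateCells()` emulates the validation cohort at reduced scale: 15
naive and 11 treated subjects, 350 cells each across CAF / tumor / immune
/ endothelial types; four CAF subtypes with 25-gene signatures planted at
3-fold over a mid-expression baseline band (so rank-matched background
genes exist on both sides); sparse NB counts (size 2) with 30% extra
dropout. C3 values are constructed so the pooled non-zero-median rule
recovers per-arm high-cell targets of 5% (naive) and 10% (treated): high
cells sit in a value band strictly above the non-zero low-expressor band,
and the low-expressor rate is chosen so the pooled median lands in the gap
between them. The C3 zero pattern is planted explicitly and therefore
exempt from the dropout mask. A per-subject logit jitter (sd 0.2) keeps
the subject random effect estimable.

**What the generators do not emulate** — and hence what green tests do
not establish about real data: gene–gene correlation beyond the planted
programs, spatial coordinates, batch structure, ambient RNA, doublets, and
the much larger biological dispersion of real cohorts. The generators are
verification harnesses for the pipeline's statistical machinery, not
realistic tissue simulators.

## Problem sizes and determinism

Every generator takes a mandatory seed and is fully deterministic given
it. The test suite exercises the numeric kernels against brute-force
oracles on 1,000 random small instances each, differential-expression
recovery on 50 default-scale spatial cohorts, survival recovery on 200
subject-level simulations plus 100 stratification chains at n = 60, and
the single-cell stage on 50 reduced-scale cohorts plus 200 subject-level
permutations — sizes chosen so the whole suite completes comfortably on a
single CPU while keeping each power bound's Monte Carlo error small
relative to its margin.

## Known limitations

- The responder latent variable mediates both the complement subgroup and
  survival; the generator makes no causal claim, it reproduces the
  observed association structure.
- The Cox stage offers no proportional-hazards diagnostics beyond the
  separation flag, no time-varying covariates and no competing risks.
- The EASE surrogate reproduces the *form* of portal enrichment analysis,
  not any specific annotation release.
- Mixed-model inference is Wald-based; with very few subjects per arm the
  one-tailed p-values inherit the usual Wald small-sample optimism.
- Gene symbols are case-sensitive exact strings with no alias resolution:
  the pipeline targets fixed-panel assays, and silent alias matching would
  be riskier than a loud missing-gene warning.
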