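# SpatialComplement

Segmented spatial transcriptomics (GeoMx DSP-style) analysis of how
neoadjuvant therapy (NAT) remodels the tumor microenvironment (TME) of
pancreatic ductal adenocarcinoma (PDAC), built around the five-gene
complement panel **C3, C1S, C1R, C4B, C7**. The package is for
computational biologists analysing segmented DSP cohorts in which each
region of interest (ROI) is split into a carcinoma (pan-CK+) and a TME
(SMA+) segment, and who want a tested, end-to-end path from probe-level
counts to patient stratification, survival analysis and single-nucleus
validation.

## What it computes

**QC and normalization.** Segments are kept when raw reads ≥ 1,000 and
aligned/trimmed/stitched rates ≥ 80%. Probes collapse to genes by geometric
mean; the per-segment limit of quantification is

    LOQ(s) = max(2, GM_neg(s) · GSD_neg(s)²)

from the negative-control probes (GM = geometric mean, GSD = geometric SD).
A gene is *detected* when its value exceeds LOQ(s); segments detecting < 1%
of genes are removed, then genes detected in < 5% of segments. Q3
normalization divides each segment by `Q3(s) / GM(Q3)` so all third
quartiles equalize.

**Differential expression.** Per gene, OLS of the log2 subject-wise mean
expression (per compartment) on a treatment indicator plus age, sex, grade
and stage; two-sided t-based p, raw p < 0.05 as in standard DSP practice.

**Signatures and enrichment.** Signature scores are geometric means of
member-gene expression (CAF programs, malignant states/lineages, immune
exhaustion). Over-representation uses the hypergeometric upper tail with
the conservative EASE `k−1` modification and Benjamini–Hochberg FDR.

**Stratification and survival.** Subject-level TME means of the complement
panel are clustered (Ward linkage, Euclidean distance on log2 values) and
cut at k = 2; the cluster with the larger mean panel value is the
high-complement subgroup. Kaplan–Meier/log-rank and a multivariate Cox
model (Efron ties; subgroup, age, sex, tumor size, grade, margin) quantify
the survival contrast.

**Single-nucleus validation.** CAF subtypes are assigned when a cell's
signature score (mean log2 normalized expression) exceeds a rank-matched
background score; C3-high cells are those above the median of non-zero C3
values; arm contrasts use `log2(GE) ~ treatment + (1|subject)` (linear
mixed model) and a binomial GLMM on the high-cell flags, with one-tailed
p-values in the pre-registered direction (treated > naive).

**Synthetic cohorts.** `generateSpatial()` / `generateCells()` emulate the
study design (13 naive vs 23 NAT subjects, 2–5 ROIs each; 15 vs 11
subjects at reduced cell counts) with negative-binomial counts and planted
effects recorded in truth manifests, so every stage is verifiable offline.

## Worked example

```r
library(SpatialComplement)
library(SummarizedExperiment)

sim <- generateSpatial(spatialSimConfig(seed = 1))
qc  <- segmentQC(sim$probes)
em  <- collapseProbes(qc$counts)
loq(em) <- computeLOQ(qc$counts)
nm  <- q3Normalize(detectionFilter(em)$exprs)

de <- fitTreatmentDE(subjectAverage(nm, compartment = "TME"))
subset(de, gene %in% complementPanel(),
       select = c(gene, estimate, p_value))
#>   gene estimate      p_value
#> 1   C3 1.389209 4.555374e-09
#> 2  C1S 1.476222 4.145730e-09
#> 3  C1R 1.389584 7.317658e-09
#> 4  C4B 1.327356 3.181512e-08
#> 5   C7 1.477052 2.173673e-09

st <- stratifyComplement(complementSubjectScore(nm)$panel_matrix)
st
#> SubgroupAssignment: 9 high / 14 low of 23 subjects

sv <- sim$survival[names(st$labels), ]
sv$subgroup <- st$labels
kmLogrank(sv, st$labels)$p
#> [1] 0.04914076
coxPH(sv)$table[1, c("term", "hr", "lo", "hi", "p")]
#>           term         hr         lo       hi           p
#> 1 subgrouphigh 0.09667646 0.02028338 0.460788 0.003362919
```

All five planted complement genes come back upregulated in the treated TME
(log2 fold ≈ 1.4: the arm-level 2-fold induction plus the responder
subgroup's extra elevation averaged over the arm); clustering the panel
splits the 23 treated subjects 9 high / 14 low, exactly the planted
responder set; and the high-complement subgroup shows significantly better
overall survival (log-rank p ≈ 0.049; adjusted hazard ratio ≈ 0.10 against
a simulated true value of 0.2 at n = 23).

For the single-nucleus stage:

```r
cells <- generateCells(cellSimConfig(seed = 2))
cm <- normalizeCells(cells$cells)
fl <- flagHighExpression(cm, "C3",
                         population = function(md) md$cell_type == "CAF")
gp <- glmmProportionTest(fl, segmentData(cm))
round(gp$pct, 2); signif(gp$p_one_tailed, 3)
#> naive   NAT
#>  4.23  9.89
#> [1] 2.72e-11
```

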