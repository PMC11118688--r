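Package: SpatialComplement
Title: Segmented Spatial Transcriptomics Analysis of Treatment-Induced
    Complement Remodeling in the Tumor Microenvironment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for segmented (GeoMx DSP-style) spatial
    transcriptomics of pancreatic ductal adenocarcinoma treated with
    neoadjuvant therapy versus upfront surgery. Covers probe-level quality
    control, negative-probe limit-of-quantification detection filtering,
    Q3 normalization, covariate-adjusted subject-level differential
    expression between compartments and treatment arms, geometric-mean
    gene-signature scoring, EASE-style over-representation analysis,
    complement-panel patient stratification with Kaplan-Meier and Cox
    proportional-hazards survival models, and a single-nucleus RNA-seq
    validation stage with rank-matched background scoring and mixed-model
    proportion tests. Includes negative-binomial synthetic-data generators
    that emulate the study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
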