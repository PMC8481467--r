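Package: exomeGxE
Title: Gene-Based Rare-Variant Gene-by-Smoking Interaction Tests for
    Pulmonary Function
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery-stage analysis of rare and low-frequency exonic
    gene-by-smoking interaction effects on quantitative pulmonary-function
    traits (FEV1, FVC, FEV1/FVC). Provides set-based variance-component
    score tests of gene-by-environment interaction and joint tests of
    genetic main plus interaction effects, with a kinship-aware null model
    for related samples; phenotype preparation (residual-outlier exclusion
    and rank-based inverse-normal transformation); variant- and gene-level
    genotype quality control with binomial imputation of missing genotypes;
    single-variant follow-up and conditional analysis; Stouffer weighted-Z
    p-value meta-analysis with genomic-control screening; and a synthetic
    multi-cohort generator so the full workflow is testable without access
    to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
biocViews: StatisticalMethod, GeneticVariability, SNP, GenomeWideAssociation
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'gene-tests.R'
    'genotype-qc.R'
    'io.R'
    'meta.R'
    'null-models.R'
    'phenotype.R'
    'pipeline.R'
    'power.R'
    'quadform.R'
    'simulate.R'
    'single-variant.R'
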