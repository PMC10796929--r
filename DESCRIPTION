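Package: TrajGEE
Title: Longitudinal GWAS of Cognitive Trajectories via Generalised
    Estimating Equations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of repeated
    cognitive measures modelled as piecewise-linear trajectories with a
    knot point one year after baseline. Per-variant models are fitted by
    generalised estimating equations with robust (sandwich) standard
    errors, testing additive variant effects on the baseline level, the
    age-at-baseline gradient, and both trajectory slopes. Includes a
    synthetic trial-cohort generator with genotype-dependent selection
    into the study, variant quality control (call rate, exact
    Hardy-Weinberg test, minor allele frequency, imputation quality,
    expected minor allele count), genotype principal components, a
    selection-bias diagnostic based on GWAS of age and sex, genomic
    control, greedy LD clumping, polygenic score construction and
    trajectory association, and an end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    sandwich,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, StatisticalMethod, Regression,
    SNP, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
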