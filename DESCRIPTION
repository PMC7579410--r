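Package: lfqtime
Title: Longitudinal Label-Free Plasma Proteomics: Grouping, Filtering,
    Imputation, Per-Protein ANOVA and Profile Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for repeated-measures label-free quantification
    (LFQ) proteomics timecourses, built around a six-individual, ten-timepoint
    immunization design. Implements in-silico tryptic digestion and
    majority-protein-group assembly under a shared-peptide rule, diagnostics
    for duplicated (whole-genome-duplication paralog) proteins relative to
    group structure, presence filtering, log2 transformation, iterative
    random-forest imputation of missing LFQ values, per-protein one-way ANOVA
    with Benjamini-Hochberg control and the corresponding R-squared threshold,
    Tukey compact letter displays, PCA, and seriated correlation-based
    hierarchical clustering of temporal profiles. A synthetic cohort generator
    reproduces the statistical structure of such studies (dominant
    individual-level variance, archetypal temporal responses,
    low-abundance-biased missingness) so the full pipeline is testable without
    raw LC-MS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    car,
    nortest,
    ranger,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
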