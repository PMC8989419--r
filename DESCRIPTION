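Package: prmepi
Title: Surfactant-Protein SNP Association and Epistasis Analysis for
    Persistent Respiratory Morbidity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-control analysis of surfactant-protein gene variants
    against persistent respiratory morbidity after paediatric acute
    respiratory failure.  Implements the 14-SNP panel data model with
    TSV/VCF genotype input, per-SNP quality control (allele counts,
    exact Hardy-Weinberg test), chi-square/Fisher group comparisons,
    carrier-model univariate logistic screening with multivariate
    backward elimination, and a quantitative-genetics SNP-SNP
    interaction sweep: additive/dominant effect types over one-, two-
    and three-SNP subsets, multi-locus genotype partitions,
    covariate-stratified Cochran-Mantel-Haenszel odds ratios,
    covariate-adjusted logistic p-values and Benjamini-Hochberg FDR
    control.  A seeded synthetic-cohort generator with planted
    single-SNP and epistatic effects supports power and error-control
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
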