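Package: scarscape
Title: Whole-Genome Scar Genotyping of Metastatic Prostate Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-sample extraction of whole-genome "genomic scar" features
    from somatic variant catalogs, copy-number segments and structural
    variants: tumor mutational burden, a microsatellite-instability InDel
    rule, kataegis detection by globally optimal piecewise-constant
    segmentation of inter-mutation distances, criteria-based
    chromothripsis calling, mutational-signature refitting (non-negative
    least squares) and de novo extraction (non-negative matrix
    factorization with rank-selection diagnostics), unsupervised
    genotype clustering with optimal leaf ordering, bootstrap support and
    Fisher-exact enrichment testing, and enhancer-versus-gene copy-ratio
    classification.  Includes a synthetic cohort generator that plants
    eight metastatic castration-resistant prostate cancer genotypes with
    full truth labels so that every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    Rcpp,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
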