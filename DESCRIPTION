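Package: ssgblup
Title: Single-Step Genomic Evaluation and Association Mapping for
    Repeated Fertility Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the genetic evaluation of lowly heritable,
    repeatedly recorded fertility traits such as days open in dairy
    cattle.  Implements the repeatability animal model with herd-year,
    additive genetic and permanent-environment effects; pedigree
    relationship matrices (A, its sparse inverse with inbreeding, A22)
    and the VanRaden genomic relationship matrix with blending and
    tuning; the single-step H-inverse; average-information REML with EM
    fallback for variance components, heritability and theoretical
    accuracy; back-solving of SNP effects from genomic breeding values
    with sliding-window variance decomposition and gene annotation; and
    a gene-dropping simulator that generates pedigrees, genotypes and
    phenotypes with the exact covariance structure assumed by the model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
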