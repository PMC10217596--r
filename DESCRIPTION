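Package: lncsnp
Title: Candidate Selection and Case-Control Association Analysis for
    SNPs in Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying single nucleotide polymorphisms (SNPs)
    located in long noncoding RNA (lncRNA) genes and testing their
    association with disease in case-control cohorts.  Implements a
    three-stage candidate-selection pipeline (tumor-vs-normal differential
    expression, GWAS-catalog/genomic-interval intersection with a minor
    allele frequency filter, and a subtype differential-expression filter,
    followed by ranking on reported odds ratios), Hardy-Weinberg
    equilibrium testing, odds ratios with Wald confidence intervals under
    codominant, dominant, recessive and overdominant genetic models,
    likelihood-ratio (G) association tests, EM estimation of two-locus
    haplotype frequencies from unphased genotypes with linkage
    disequilibrium statistics (D, D', r-squared), haplotype-level
    association, and stratified analyses over clinical covariates.  A
    synthetic-cohort generator with analytic ground truth makes every
    stage testable without external data, and genotype counts from a
    published Brazilian breast-cancer case-control cohort are bundled as
    golden reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
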