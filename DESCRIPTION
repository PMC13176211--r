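Package: germprint
Title: Genotype Quality Control, Population Structure, and SNP
    Fingerprinting for Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-variant-calling toolkit for plant germplasm panels:
    reads multi-sample VCF genotypes into a dosage matrix, applies
    sample- and site-level quality control with attrition bookkeeping
    (missingness, Hardy-Weinberg exact test, minor allele frequency,
    windowed linkage-disequilibrium pruning, inbreeding-coefficient and
    relatedness screens), computes diversity and differentiation
    statistics (observed/expected heterozygosity, polymorphic
    information content, nucleotide diversity, weighted Weir-Cockerham
    FST, LD-decay profiles), infers population structure (maximum
    likelihood admixture via EM with hold-out cross-validation,
    allele-frequency-scaled PCA, k-means/silhouette validation,
    identity-by-state UPGMA trees), and designs compact SNP
    fingerprinting panels with probability-of-identity metrics and
    checksummed barcode payloads. Includes a Balding-Nichols cohort
    simulator with admixture, distance-dependent linkage
    disequilibrium, and plantable quality-control defects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
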