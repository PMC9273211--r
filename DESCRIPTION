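Package: paleodater
Title: Dating Archaic-Modern Gene Flow from Haplotype Lengths and Pairwise Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gamma-posterior dating of the common ancestor of two chromosomes
    from pairwise sequence differences and/or shared-haplotype length, with a
    branch-shortening correction for ancient samples and truncated confidence
    intervals; an incomplete-lineage-sorting test based on expected shared
    tract lengths; recombination-map repair and genetic-length queries;
    genotype-matrix procedures for ancestral-allele polarization, informative
    site ascertainment, window divergence scans, r-squared haplotype tagging,
    clade splitting and an allele-frequency-trajectory test in dated cohorts;
    a permutation test for enrichment of missense variants in a Gene Ontology
    derived gene set; and seeded synthetic-data generators so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
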