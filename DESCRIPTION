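Package: hybridsig
Title: Genomic Signatures of Homoploid Hybrid Speciation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for homoploid hybrid speciation from population genomic
    data: a rooted gene-tree topology census with a coalescent (ILS-only)
    simulation null, population-level ABBA-BABA D statistics and a
    site-pattern invariant hybrid test with admixture-proportion estimation,
    classification of inter-group fixed long indels into phylogenetically
    informative and ancestral variation classes with chi-square signal
    tests, and a positive-selection scan that assigns selected alleles of
    the hybrid lineage to a parental lineage. A multispecies-coalescent
    simulator with a hybrid edge generates gene trees, variant tables and
    codon alignments so that every stage of the pipeline can be exercised
    and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vcfR,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
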