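Package: syndup
Title: Synteny, Duplication Architecture and Expression Divergence of Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise how a labelled gene family (such as the
    F-box family of SCF E3 ubiquitin ligases) is distributed across the
    duplication architecture of plant genomes. Calls family members from
    profile-HMM domain-hit tables using an e-value and domain-coverage
    filter, detects syntenic blocks, tandem arrays and segmental
    duplications from all-vs-all protein homology anchors by
    dynamic-programming chaining in gene-rank space, tests family
    enrichment inside those structures with a label-shuffling permutation
    null, and quantifies transcriptional divergence of duplicated genes
    from tissue expression matrices. Includes a genome simulator with
    known whole-genome-duplication, segmental and tandem histories so the
    whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
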