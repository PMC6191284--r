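Package: genelossr
Title: Detection, Validation and Molecular Dating of Gene Loss in Coding Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene loss in comparative genomic data:
    scanning aligned coding sequences for gene-inactivating mutations
    (premature stop codons, frameshifting indels, splice-site disruptions
    and exon deletions), validating candidate mutations against unassembled
    sequencing reads, placing loss events on a time-calibrated phylogeny by
    Dollo parsimony, estimating dN/dS under branch models with fixed
    pseudogene classes by maximum likelihood, and converting the mixed
    dN/dS observed on a loss branch into a calendar-date interval for the
    inactivation event.  Includes a codon substitution simulator with a
    functional-to-neutral regime switch so every stage can be exercised on
    data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
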