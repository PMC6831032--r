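Package: mytBTN
Title: Detection and Quantification of Bivalve Transmissible Neoplasia in
    Mytilus Mussels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-locus inference workflow that distinguishes conventional
    disseminated neoplasia from bivalve transmissible neoplasia (BTN) in
    Mytilus mussels.  Curates cloned Sanger allele sequences with
    singleton-collapse and PCR-chimera filters, detects supernumerary and
    shared cancer-associated alleles across diseased individuals, places
    alleles on neighbor-joining trees to assign the cancer lineage's species
    of origin, scans mitochondrial alleles for female/male recombination
    breakpoints and control-region tandem repeats, quantifies cancer-allele
    fractions from allele-specific qPCR with limit-of-detection rules, and
    classifies samples from diagnostic-SNP (KASP) fluorescence panels.  A
    synthetic-cohort generator with exported planted truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
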