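Package: assocpipe
Title: Pipelined Association Testing Beyond Genome-Wide Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified, pipelined toolkit for case-control and quantitative
    association analysis beyond single-marker genome-wide scans: main-effect
    SNP scans, gene-gene and gene-environment interaction likelihood-ratio
    tests, phenome-wide association scans with automatic regression-type
    detection, copy-number-variant burden and burden-by-environment tests, a
    rank-based permutation test for gene-level CNV enrichment, and
    Madsen-Browning-weighted rare-variant burden regression.  Includes
    readers and writers for PLINK PED/MAP and BED/BIM/FAM, VCF, trait and
    CNV-call tables, QC filters, minor-allele recoding, genetic encodings,
    an in-house linear/logistic/Firth regression engine with permutation
    p-values, multiple-testing corrections, and deterministic synthetic-data
    generators so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
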