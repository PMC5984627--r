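Package: fosfuse
Title: Characterisation of Promoter-Preserving FOS/FOSB Rearrangements
Version: 0.1.0
Authors@R:
    person("fosfuse", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterising the FOS/FOSB-type
    rearrangements found in benign bone tumours: break-end annotation
    against gene models, reconciliation of DNA- and RNA-supported break
    points, reconstruction of the predicted fusion transcript with
    reading-frame and stop-codon classification, detection of cryptic
    polyadenylation sites from per-base RNA coverage drops,
    allele-specific expression at heterozygous SNPs, and rule-based
    driver screening of small variants, copy-number segments and
    structural variants. Ships a fully deterministic synthetic-genome
    simulator with ground truth so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
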