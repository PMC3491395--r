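Package: pseudoDecoR
Title: Pseudogene Activity Decoration from Functional Genomics Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates annotation consensus, parent-gene sequence identity,
    RNA-seq transcription evidence, substitution-based conservation testing,
    chromatin-state segmentation, and upstream ChIP-seq regulation into a
    per-pseudogene activity table (a psiDR-style decoration resource).
    Provides a consensus merger for manual and automated pseudogene call
    sets with evidence levels, rule-based transcription callers, a Poisson
    conservation test with Benjamini-Hochberg selection, a segmentation
    label-frequency classifier for active chromatin, Pol2/promoter/TFBS
    upstream activity calls, tissue-specificity Jaccard matrices,
    partial-activity classification, and a synthetic-corpus generator with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
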