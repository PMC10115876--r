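Package: abeprofiler
Title: Adenine Base Editing Outcome Quantification and Off-Target Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for adenine base editing (ABE) experiments
    correcting the haemoglobin E (HbE) codon-26 variant of HBB: classification
    of per-read codon editing outcomes from paired amplicon sequencing,
    in-silico and CIRCLE-seq-based off-target site nomination with adenine
    editing-window filtering and ranking, deamination-frequency estimation and
    off-target calling from ultra-deep targeted capture alignments,
    sequence-based chromatin-accessibility damage scoring of candidate edits
    with a pluggable predictor, cryptic splice-junction quantification from
    spliced alignments, and delta-delta-Ct relative expression statistics.
    Includes seeded synthetic-data generators emitting every input format the
    pipeline consumes together with machine-readable truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
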