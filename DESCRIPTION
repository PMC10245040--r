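Package: svjunction
Title: Structural-Variant Breakpoint Junction Detection and ctDNA Quantification
Version: 0.1.0
Authors@R: person("Anon", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Tumor-informed circulating tumor DNA (ctDNA) analysis built
    around patient-specific structural-variant (SV) breakpoint junctions.
    Provides high-confidence SV selection from caller output (score,
    repeat/gap, recurrence and copy-number-step filters), construction of
    junction reference sequences, fuzzy-matching classifiers for
    multiplex-PCR amplicon read pairs and for soft-clipped whole-genome or
    hybrid-capture reads, UMI-aware molecule counting, control-thresholded
    detection calling, linear and Poisson-corrected allele-fraction
    estimators with theoretical limit-of-detection and assay-design math,
    in-silico cell-free DNA fragment size selection, and seeded simulators
    that generate every input with machine-readable truth files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
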