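Package: rrsnp
Title: Reduced-Representation SNP Discovery from Short Sequence Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing reduced-representation
    sequencing experiments for SNP discovery between two pooled inbred
    parents. Provides IUPAC-aware in-silico restriction digestion with
    fragment size selection and an enzyme evaluation metric panel,
    a synthetic two-parent genome and 33-mer tag read simulator with
    Gamma-overdispersed coverage and repeat-driven pile-up, a
    seed-and-verify ungapped tag aligner with a mapping-quality proxy,
    pileup-based SNP calling with lenient and stringent filter ladders,
    cross-assembly exclusion and flanking-context extraction, and the
    survey statistics used to characterise coverage bias, clone library
    quality and validation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
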