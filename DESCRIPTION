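Package: becall
Title: Base-Editing Allele Classification, Embryo Genotyping, and Off-Target Variant Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cytidine base-editor outcomes in subcloned
    amplicon sequences: per-clone allele calling against a reference amplicon
    with a guide/protospacer coordinate model, classification of substitutions
    into canonical-window, on-target, target-strand, non-canonical and
    proximal-site deamination events, aggregation of clone pools into embryo
    genotypes (wild-type, heterozygous, biallelic, homozygous, mosaic) and
    experimental-group summaries with chi-square comparisons. Also implements
    a whole-genome-sequencing off-target candidate triage: known-variant
    removal, low-complexity interval overlap, flank homopolymer filtering,
    and guide-site matching under a mismatch budget or a perfect 3' seed with
    an NGG PAM. A synthetic-data module generates clone pools under a
    per-position deamination model and toy genomes with planted guide sites,
    homopolymer runs, low-complexity intervals and variant candidates, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
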