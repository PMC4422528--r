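Package: enulift
Title: Exon Annotation Lift-Over and Inheritance-Model Variant Filtering
    for Mutagenized Mouse Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotyping support for mutant mouse lines sequenced against a
    closely related but un-annotated strain assembly. Exon and gene
    annotations are lifted from an annotated source assembly onto the target
    assembly by best single-hit local alignment of exon sequences (a built-in
    k-mer seed-and-extend aligner, or externally computed tabular hits),
    written as BED features, and attached to multi-sample VCF records as INFO
    tags. Candidate causative mutations are then isolated by a multi-line
    filtering cascade: inheritance-model genotype selection, cross-line
    privacy, exon/gene containment, one-variant-per-gene exclusion, optional
    linkage-region restriction, and flagging of ENU-typical base changes. A
    fully deterministic simulator generates diverged genome pairs, exon
    catalogs, and multi-line cohorts with planted causative variants for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
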