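Package: spliceko
Title: CRISPR Knockout Validation from Alignments: Indel Genotyping,
    Consequence Classification and Exon-Retention Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates CRISPR knockouts from standard alignment files.
    Extracts insertions and deletions overlapping CRISPR target sites from
    the CIGAR strings of amplicon (Sanger-clone) alignments, summarises
    per-individual allele composition and mosaic mutant-allele fractions,
    classifies each indel against a transcript model into loss-of-function,
    splice-site or in-frame consequences, quantifies exon skipping from
    junction-spanning RNA-seq reads as percentage exon retention (PIR), and
    applies a counts-per-million minimum-expression filter to gene-level
    count matrices. A seeded synthetic-data generator emits reference FASTA,
    GFF3 gene models and pre-aligned SAM reads with truth tables so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments
Config/testthat/edition: 3
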