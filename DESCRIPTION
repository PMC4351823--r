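Package: hml2tx
Title: In Silico Splicing, Locus Assignment and Retrocopy Detection for
    HERV-K(HML-2) rec and np9 Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transcription of the human endogenous
    retrovirus group HERV-K(HML-2). Models the canonical type 2 provirus
    anatomy, classifies proviral loci as type 1 or type 2 by the 292-bp env
    discriminator, annotates splice donor/acceptor sites, assembles in silico
    spliced env/rec/np9 isoforms and predicts multiplex degenerate-primer PCR
    amplicons, assigns cDNA reads to genomic loci by diagnostic mismatches,
    detects alternative splice variants and transcripts from loci absent from
    the reference assembly, screens loci for Rec/Np9 coding capacity, and
    detects L1-mediated retrocopies of spliced mRNAs by target site
    duplication, poly-A and exon-junction hallmarks. Ships a seeded synthetic
    data generator emulating a multi-tissue Sanger cDNA survey so the whole
    pipeline is testable without external downloads.
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
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
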