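Package: vestigr
Title: Detection and Classification of Vestigial (Pseudogenized) Gene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for deciding whether a gene survives as a
    functional locus or as a pseudogenized relict in a query genome.  The
    pipeline anchors the candidate locus by chaining single-copy marker genes
    shared with a reference genome (synteny), reconstructs a degraded exon
    model inside the anchored interval with a frameshift-aware
    protein-to-genome spliced aligner seeded by conserved peptide motifs,
    classifies gene-inactivating lesions (frameshift, premature stop,
    splice-site loss, start loss) on the reconstructed open reading frame,
    and weighs predicted-exon transcription against an intergenic
    transcriptional-noise null using RPKM and TPM.  A companion simulator
    generates genomes, diverged orthologs with recorded lesion truth sets,
    and mapped-read sets so that every stage is verifiable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
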