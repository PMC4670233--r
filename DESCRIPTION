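Package: EditScape
Title: Detection, Quantification and Phasing of A-to-I RNA Editing from
    RNA-Seq and Targeted Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for A-to-I RNA editing analysis in
    model-organism transcriptomes. Detects candidate editing sites and
    dense hyperediting clusters from aligned RNA reads; quantifies
    per-site editing levels from targeted multiplex-PCR amplicon
    sequencing with a quality-score/coverage/incidence filter cascade,
    genomic-SNP masking against matched gDNA, and off-target site
    discovery; phases adjacent editing sites on single reads into mRNA
    variant abundances with protein-recoding labels; profiles mismatch
    spectra, nucleotide neighbor preferences, genomic-feature and
    repeat-family enrichment of edited sites; scans for FMRP RNA
    recognition elements (ACUK/WGGA); and ships a fully seeded synthetic
    data generator with truth tables so every stage can be exercised and
    verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
biocViews: Transcriptomics, RNAEditing, Sequencing, Software
RoxygenNote: 7.3.3
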