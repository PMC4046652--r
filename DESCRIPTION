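Package: allosnp
Title: Simple SNP Discovery and GoldenGate Genotyping Analysis for
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of "simple" (single-locus allelic) SNPs in an
    allotetraploid genome from short-read resequencing of an inbred
    accession panel, with the homoeolog-aware filters that separate
    allelic variation from inter-subgenome divergence. Implements
    repeat masking, unique-alignment read classification, a four-step
    homozygosity/depth/minor-allele filter cascade, transition/
    transversion and coding-effect annotation, GO term enrichment with
    a Fisher fallback, and two-channel (Cy3/Cy5) GoldenGate theta
    clustering with hemi-SNP detection and segregation tests. A seeded
    synthetic-data generator emulates an A+C allotetraploid reference,
    inbred panel, reads, gene models and genotyping intensities with a
    machine-readable truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
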