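Package: genopept
Title: Proteogenomic Peptide Discovery and Annotation Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for proteogenomic mapping of mass-spectrometry peptides
    onto a genome and for comparing expressed products against two independent
    reference annotations. Builds partitioned six-frame translation search
    databases with coordinate-recoverable headers and per-entry shuffled
    decoys; filters peptide-spectrum matches by E-value, per-spectrum best
    match and spectral-count rules, and estimates target-decoy false discovery
    rates; maps peptides exactly onto six-frame translations of the genome and
    classifies single-locus novel peptides into ten annotation-relative
    categories (intergenic, intron, UTR, out-of-frame, terminal extensions);
    classifies assembled transcripts against reference gene models by
    intron-chain comparison; transfers miRNA names by coordinate proximity;
    and generates fully synthetic genomes, annotation pairs, peptides, PSM
    tables and transcripts with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
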