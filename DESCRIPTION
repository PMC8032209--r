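Package: circmotif
Title: Back-Splice Junction Motif Discovery and Genetic Constraint for Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline around the observation that circularization of
    RBM20-dependent TTN circRNAs creates a functional sequence motif at the
    back-splice junction. Builds back-splice and linear exon-junction
    sequences from a genome and exon annotation, discovers the shared
    junction-spanning consensus of a circRNA class by exhaustive k-mer
    voting, runs IUPAC motif enrichment comparisons across circRNA sequence
    classes (Fisher exact with Benjamini-Hochberg adjustment), computes
    regional genetic constraint as observed/expected rare variants under a
    trinucleotide-context neutral mutation model with methylation strata and
    sequencing-depth correction, and derives exon-composition bounds for
    large circRNA isoforms from exon-inclusion matrices. A synthetic-data
    module generates a TTN-like locus with planted junction motifs and
    Poisson-sampled rare variants so that every stage runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
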