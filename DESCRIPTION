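Package: srnakit
Title: Modular Small RNA-Seq Quantification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular toolkit for quantifying the small RNA'ome from small
    RNA sequencing data. Provides quality control of raw reads (adapter
    trimming, removal of randomized ligation bases, PHRED-based filtering and
    length selection), genome alignment ingestion plus a built-in exhaustive
    micro-aligner for self-contained testing, overlap-ratio based annotation
    of multiple small RNA classes (miRNA, piRNA, snRNA, snoRNA, tRNA,
    circRNA) with explicit multi-mapper counting rules and no type priority,
    taxonomic counting of genome-unmapped reads against a phylogenetic tree,
    and sample-level merging, counts-per-million normalization and
    nonparametric (Mann-Whitney) differential expression. A fixtures module
    generates deterministic synthetic genomes, feature databases, reads and
    taxonomies so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    BiocGenerics,
    methods,
    Rsamtools,
    ShortRead,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
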