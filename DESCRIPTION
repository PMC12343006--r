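Package: exdup
Title: Detection and Classification of Within-Gene Coding Exon Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and classifies duplications of protein-coding exons within
    the boundaries of their parent genes, from a genome assembly (FASTA) and a
    gene annotation (GFF3/GTF). Implements representative-exon selection by
    deterministic interval clustering, a translated six-frame local similarity
    search of each representative exon against its whole gene, a global
    search over representative exon pairs, classification of matches against
    exon/intron boundaries (full-length, partial, inter-boundary, intronic),
    reconciliation of overlapping target intervals with reading-frame
    assignment, graph-based grouping of related exon copies into expansions,
    tandemness and transcript-interdependence classification, a relational
    results store with CSV export, and a synthetic-genome simulator with
    recovery scoring for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
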