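Package: pacscan
Title: Genome-Wide Poly(A) Site Cluster Discovery from Bulk RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines non-templated poly(A)/poly(T) tails from standard RNA-seq
    reads to map cleavage sites genome-wide, clusters them into poly(A) site
    clusters (PACs), filters internal-priming artifacts, annotates PACs against
    gene models with a data-driven 3'-UTR extension, classifies alternative
    polyadenylation (strong/weak/medium PAC usage), and profiles nucleotide
    composition and near-upstream-element (NUE) hexamer enrichment around
    cleavage sites. Includes a fully specified synthetic-data generator
    (genome, GFF3 annotation, FASTQ reads with ground truth) and an exact-match
    test aligner so the whole pipeline is testable without external data.
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
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
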