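Package: bchrom
Title: Supernumerary B-Chromosome Detection and Candidate-Gene Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free assignment of assembly contigs to the standard (A)
    complement or a supernumerary B chromosome by comparing +B and 0B short-read
    k-mer coverage over diagnostic low-copy k-mers, with downstream screening of
    B-encoded candidate genes: per-stage two-group differential expression from
    raw counts, hypergeometric gene-ontology enrichment against a B-only gene
    universe with terminal-term selection, affine-gap global alignment of A/B
    protein variants, and tandem-repeat co-occurrence scanning. Includes a
    synthetic-data generator (genome, +B/0B reads, negative-binomial counts,
    ontology annotations, protein variant pairs) with ground-truth tables so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
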