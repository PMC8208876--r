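Package: mitokit
Title: Comparative Analysis Toolkit for Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of small organellar genomes,
    built around fungal endosymbiont mitochondria. Detects perfect simple
    sequence repeats (SSRs) with unit lengths of 1-10 bp and classifies
    them under a three-tier normal / extended / potential scheme;
    classifies genomic intervals as genic, intronic-ORF, intronic or
    intergenic against a gene feature table; identifies intraspecific
    SNPs, insertions and deletions from a whole-genome multiple sequence
    alignment with protein-effect annotation under the mold mitochondrial
    genetic code; concatenates per-gene alignments into a supermatrix and
    reconstructs neighbor-joining trees with bootstrap support; and
    generates synthetic mitogenome-like data with ground-truth manifests
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
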