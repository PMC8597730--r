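Package: pseudonif
Title: Detection of Pseudo-nifH Genes in Genomes and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect "pseudo" nifH genes, i.e. nifH homologs unlikely
    to take part in nitrogen fixation, from prokaryotic genome annotations and
    shotgun metagenomes. Classifies every nifH coding sequence as operonic
    (T1), split (T2) or stand-alone (T3) from gene-neighborhood and genome
    cooccurrence of nitrogenase subunit genes (nifD/nifK and their vnf/anf
    counterparts); crosswalks genomes against a diazotrophy phenotype table;
    quantifies the confusability of short NifH fragments with exact global
    alignment and sequence similarity networks; and screens paired-end
    metagenomes into true/pseudo/ambiguous nifH read counts with a Poisson
    gene-length proportionality test. Includes a synthetic-data generator
    (annotated genomes, two-clade protein families, paired-end reads with
    known origins) so the whole pipeline is testable without database
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
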