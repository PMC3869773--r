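Package: polpool
Title: Pool Classification of RNA Pol II ChIP-seq Signal and PARP-14 Motif
    Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes in T helper 2 (Th2) cells by their dependence
    on PARP-14 and on ADP-ribosyltransferase (ART) activity from RNA
    polymerase II ChIP-seq average peak values measured in four conditions
    (wild type, Parp14-knockout, each with and without the pan-PARP
    inhibitor PJ34) plus an input control.  Implements the nested
    fold-change decision tree that builds the active-transcription gene
    pool and splits it into PARP-14-dependent and ART-dependent
    sub-pools, hypergeometric gene-set enrichment with Benjamini-Hochberg
    correction, mismatch-tolerant scanning of promoters and gene loci for
    fixed DNA motifs, simplified exhaustive k-mer de novo motif discovery
    under a zero-or-one-occurrence-per-sequence (ZOOPS) model, three-way
    gene-list overlap analysis, and a synthetic-data generator that plants
    known dependence classes and motif occurrences for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
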