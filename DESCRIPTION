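Package: eicir
Title: Detection and Quantification of Exon-Intron Circular RNAs from Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects exon-intron circular RNAs (EIciRNAs) from paired-end
    RNA-seq data starting from back-splice junction (BSJ) calls. Assigns host
    transcripts to circRNA calls by exon-boundary scoring, re-places
    BSJ-supporting read pairs on rotated circular pseudo-references to find
    intronic evidence, validates intron retention with junction and coverage
    metrics (#EE, #EI, #IE, #I, #IC and percent intron retention), quantifies
    EIciRNAs as back-spliced reads per million (BRPM), computes the tau
    tissue-specificity index, classifies retained introns (CIR, NCI, LIR),
    and trains a three-hidden-layer neural network on sequence-computable
    intron features with pairwise AUROC/AUPRC evaluation and permutation
    feature importance. Includes a paired-end read simulator producing toy
    genomes, FASTQ, splice-aware SAM and ground-truth tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
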