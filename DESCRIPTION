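Package: endotol
Title: Integrative Methylome and Transcriptome Analysis of Endotoxin Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for integrative analysis of lipopolysaccharide (LPS)-driven
    endotoxin tolerance in monocytes. Implements differential methylation of
    EPIC-style beta-value matrices via per-probe linear models on M-values with
    donor covariates and empirical-Bayes variance moderation; a moderated-t
    differential expression stage on log-transformed normalized counts with a
    signed -log10(FDR) ranking metric; a tolerization score for four-condition
    re-stimulation time courses with top-N tolerized gene-set construction; a
    preranked gene set enrichment analysis (GSEA) engine with a gene-label
    permutation null, normalized enrichment scores and ratio-of-tails FDR;
    CpG-centric motif-window, tile-wise peak, and genomic-category enrichment
    based on exact Fisher tests; nearest-TSS methylation-expression integration
    with hierarchical time-course clustering; and synthetic-data generators with
    known ground truth for every stage. Tibble-first interfaces, broom-style
    tidy() and glance() methods and ggplot2 plotting are provided throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    fgsea,
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
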