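Package: snclust
Title: Annotation-Independent Discovery and Classification of Small
    Non-Coding RNAs from Read Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls candidate transcripts as strand-aware read-coverage
    clusters from low-structure-bias (TGIRT-style) RNA-seq alignments,
    subtracts known annotation through a filter cascade, and classifies
    the surviving non-annotated clusters into eight small non-coding RNA
    biotypes (tRNA-like, pre-tRNA, tRNA fragment, C/D and H/ACA snoRNA,
    ITS-RNA, ETS-RNA, unknown) by integrating sequence homology,
    family-structure heuristics, box/guide motif detection and repeat
    overlap. Includes tRNA-fragment positional mapping, conservation and
    ortholog-identity scoring, TPM quantification with host-gene
    correlation, depletion-response analysis, and a synthetic-data
    generator that plants ground-truth loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
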