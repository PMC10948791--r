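Package: napkit
Title: Calling and Classifying Full-Length Noncapped RNAs from End-Tagged
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for discovering full-length noncapped RNAs (napRNAs)
    from sequencing libraries in which ligated 5' and 3' adapters mark the
    true transcript boundaries. Provides adapter and randomized-barcode
    trimming with per-end verification flags, strand-specific coverage and
    boundary signal tracks with RPM normalization, a boundary caller that
    scores candidate transcripts by six boundary/coverage statistics and
    merges calls across samples, a 5'-cap-site caller for cap-enriched
    libraries, interval- and motif-based classifiers for stable intron RNAs
    (sliRNAs), snoRNA-intron chimeras (snotrons), miRNA-spacer RNAs
    (misRNAs) and Pol III / C-D box / H-ACA box families, secondary-structure
    evidence via base-pair-maximization folding and dinucleotide-shuffle
    z-scores, mutational-profiling (SHAPE-MaP style) reactivity profiles, and
    a seeded simulator that generates complete test worlds (genome,
    annotations, truth transcripts, read libraries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    BiocGenerics,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicAlignments,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
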