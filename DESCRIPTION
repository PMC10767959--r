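Package: hcregions
Title: Heterochromatin Region Classification, Annotation and Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for heterochromatin domains defined by the repressive
    histone marks H3K9me2, H3K9me3 and H3K27me3. Reads ChIP-seq peak calls
    (ENCODE narrowPeak or BED), classifies regions as recognized by one, two
    or three marks using a strict greater-than-50-percent overlap rule,
    annotates regions against gene models (nearest gene, distance to TSS,
    promoter/UTR/exon/intron/downstream categories) and arbitrary BED
    tracks, calls differential heterochromatin regions between case and
    control samples with a conditional exact count test (binomial or
    negative-binomial), and performs hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction. A seeded
    synthetic-data generator plants multi-mark overlaps and differential
    count signals with known ground truth so every component is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
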