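Package: escapex
Title: Sex-Biased Expression Screening and X-Inactivation Escape Domain
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, synthetic-data-driven pipeline for detecting
    sex-biased gene expression across mouse tissues and for discovering
    X-chromosome domains in which a female-biased protein-coding gene is
    proximally paired with a female-biased long non-coding RNA, as seen for
    genes escaping X-inactivation. Provides per-array standardization,
    Xist-based sample-sex quality control and sex balancing; a per-probe
    Wilcoxon Mann-Whitney screen with Benjamini-Hochberg false discovery
    rate control and signed fold changes; per-chromosome over-representation
    tests; cross-tissue overlap and gene categorization; coding/non-coding
    gene pairing with a permutation null for genomic co-localization; peak
    coverage statistics for repressive histone-mark depletion over candidate
    domains; and standard-curve quantitative PCR validation with
    reference-gene normalization. A configurable simulator generates
    annotation, expression, peak and qPCR data with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
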