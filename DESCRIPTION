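Package: chemgsea
Title: Chemical Gene-Set Enrichment from GWAS, TWAS and Expression Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens environmental chemicals for association with a disease by
    combining three evidence streams at the gene level: summary-based
    transcriptome-wide association statistics (z = w'Z / sqrt(w'Lw) from GWAS
    z-scores, eQTL expression weights and an LD reference), best-SNP gene
    scores, and two-group differential-expression statistics. Each stream
    yields a ranked gene list that is tested against chemical-gene interaction
    sets with a weighted Kolmogorov-Smirnov-like running-sum enrichment score,
    a shared permutation null per set size, normalized enrichment scores and
    empirical p-values. Significant chemicals are intersected across streams
    and diseases with explicit per-tissue accounting. A synthetic-data module
    generates GWAS summaries with block LD, sparse expression weights, an
    overlapping chemical gene-set collection with planted causal sets, and a
    two-group expression matrix, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
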