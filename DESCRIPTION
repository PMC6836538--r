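Package: dese
Title: Driver-Tissue Estimation by Selective Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the driver tissues of complex traits from GWAS summary
    statistics and multi-tissue expression profiles. Implements a robust
    selective-expression z-score based on Huber regression of rank-sorted
    tissue means (plus conventional z, MAD z and RVP measures), an
    effective-chi-square gene-based association test with LD-aware
    conditioning, per-tissue Wilcoxon rank-sum enrichment of associated
    genes' selective expression, and the iterative loop that re-orders the
    conditional analysis by tissue-selectivity ranking scores until the
    tissue p-values converge. Includes a synthetic-data generator for
    expression matrices, gene models and LD-blocked GWAS z-scores so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
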