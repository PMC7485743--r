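Package: longbat
Title: Comparative Selection and Expression Analysis for Long- and
    Short-Lived Species Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for contrasting a long-lived and a short-lived
    species pair at the coding-sequence and blood-transcriptome level.
    Provides pairwise Ka/Ks estimation by Nei-Gojobori (1986) counting
    with Jukes-Cantor correction and a Fisher exact positive-selection
    test; TMM between-sample normalization and rank-based differential
    expression; per-gene crossed random-effects (REML) variance
    partitioning into species, sex and residual components with a
    high-interspecific-variance screen; hypergeometric GO
    over-representation and GO-term-level paired one-tailed Wilcoxon
    signed-rank tests; and an anti-/pro-longevity gene signature test
    judged against a gene-subsampling null summarized by its 95%
    highest density interval. A synthetic-data module generates codon
    alignments, count matrices, annotations and gene lists with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
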