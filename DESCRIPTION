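Package: dupmask
Title: Duplicate-Gene Phenotype Masking and Essentiality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phenotype masking between duplicate gene
    pairs and the contrasting evolutionary dynamics of essential and
    non-essential genes, modelled on systematic single- and double-RNAi
    knockdown screening in Caenorhabditis elegans. Provides reciprocal-best-hit
    paralog discovery with a duplicate-isolation filter, RNAi screen phenotype
    scoring and penetrance calls, a multiplicative-model masking statistic
    with a one-sided rank test, Li (1993) Ka estimation under the Kimura
    two-parameter correction, rule-based duplication-age dating from
    bootstrap-annotated gene trees, aggregate rate and trend statistics, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    withr
Config/testthat/edition: 3
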