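Package: polarnet
Title: Differential Correlation-Network Polarity Analysis for Factorial
    qPCR Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for two-genotype, two-treatment quantitative PCR
    studies: relative quantification by the 2^(-deltadeltaCt) method with
    technical-replicate handling, phenotypic trait summaries with two-way
    ANOVA and Tukey compact letter displays, trait-gene PCA integration,
    and genotype-specific Pearson correlation networks compared edge-wise
    to detect correlation polarity reversals and classify genes into
    hubs, phenotypic switchers, and contextual responders.  Includes a
    seeded synthetic-study generator with plantable ground truth (fold
    changes, correlation signs, hub structure) so the whole pipeline can
    be validated end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    multcomp,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
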