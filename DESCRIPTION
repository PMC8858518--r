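Package: csdnet
Title: Differential Gene Co-Expression Networks from Conserved, Specific
    and Differentiated Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds differential co-expression networks from two gene
    expression conditions. For every gene pair the Spearman correlation is
    estimated in each condition by bootstrap resampling, giving a mean
    correlation and its sampling variance via Welford's streaming
    algorithm. The two conditions are combined into conserved (C),
    specific (S) and differentiated (D) scores, and the highest-scoring
    pairs per score type are selected into typed edge lists. Includes a
    synthetic-data generator with planted co-expression structure, a
    seed-robustness overlap experiment, and a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
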