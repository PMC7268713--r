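Package: qsortr
Title: Q-Methodology Analysis of Forced-Distribution Q-Sorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: By-person (inverted) factor analysis for Q-methodology studies in
    which participants rank statements onto a forced quasi-normal grid.
    Implements the full quantitative pipeline: inter-sort correlation,
    principal-component extraction, Varimax rotation with optional Kaiser
    normalization, rule-based factor retention (eigenvalue and two-exemplar
    rules), exemplar flagging with significance thresholds, weighted factor
    z-score estimation, quantization of scores into grid-conforming factor
    arrays, and distinguishing/consensus statement classification. Ships the
    instrument of a published health-perception Q-study (42 statements, the
    sorting grid, factor arrays, and sample demographics) as plain-text
    fixtures, together with a synthetic Q-sort simulator with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
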