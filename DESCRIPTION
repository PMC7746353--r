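Package: tsrnakit
Title: Classification, Quantification and Target Analysis of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for transfer-RNA-derived small RNA (tsRNA)
    analysis from small-RNA sequencing data. Parses structure-annotated
    tRNA references, trims and length-filters reads, classifies distinct
    fragments into the six canonical tsRNA types (tRF-1, tRF-3, tRF-5,
    i-tRF, tiRNA-3, tiRNA-5) with a systematic naming scheme, quantifies
    fragments as tags per million of aligned tRNA reads, calls
    differential tsRNAs between groups, predicts mRNA targets by a
    three-rule consensus (seed match, strict 5'-end pairing, duplex
    free-energy threshold), intersects predictions with differentially
    expressed mRNAs, runs accumulative hypergeometric pathway enrichment,
    and exports tsRNA-mRNA-pathway networks. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
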