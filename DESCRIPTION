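Package: guideqc
Title: Internal-Interaction Screening and Activity Quantification for CRISPR-Cas9 Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens single-guide RNA spacers for internal secondary structure
    that predicts failure to form a cleavage-competent Cas9 complex:
    intra-spacer hairpins (including G:U wobble stems) and duplexes between the
    spacer and the sgRNA constant region (backbone). Ranks predicted stems with
    a transparent Nussinov-style maximum-pairing score, quantifies in vitro
    cleavage activity by fitting single-turnover dose-response curves to a Hill
    sigmoid with a fixed coefficient to obtain EC(1/2max) with censoring,
    computes somatic mutagenesis rates from read counts, and finds
    sequence-similar genomic sites with a substitution-minimizing position
    specific scoring matrix scan. Includes deterministic synthetic-fixture
    generators so every analysis is testable without external data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
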