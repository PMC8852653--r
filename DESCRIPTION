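Package: socioscope
Title: Quantitative Social Listening for Telegram Chat Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A privacy-preserving analysis pipeline for Telegram Desktop
    chat exports: parsing and eligibility screening of exported group
    chats, anonymization and pseudonymization of message text, weighted
    regex-dictionary autocoding, lemma-frequency and sentiment analytics
    aggregated per chat and per chat group with t-tests and standard
    errors, and a structured annotated export for qualitative coding.
    Includes a synthetic-corpus generator with planted, recoverable
    statistical structure so the whole pipeline can be validated without
    access to real chat data.
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
    rlang,
    stats,
    stringi,
    stringr,
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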