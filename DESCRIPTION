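Package: lexiscreen
Title: Depression Lexicon Construction, Expert Content Validation, and
    Text Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating symptom lexicons for
    screening depressive language in short text messages. Provides a
    13-category symptom taxonomy anchored in the DSM-5 and ICD-10
    depressive-episode criteria, a lexicon data structure with readers,
    writers and count summaries, combinatorial expansion of textspeak
    spelling variants for multi-word keywords, Lawshe-style expert
    content validation (content validity ratio and index, retention
    threshold with a judgment-point rescue rule), an exact phrase-matching
    screening engine producing per-category symptom tallies over message
    streams, and seeded synthetic fixtures (toy lexicons, rating panels,
    message streams with ground truth) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
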