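Package: atcmapr
Title: Standardize Free-Text Medication Entries into ATC Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dictionary-based pipeline that transforms heterogeneous
    (German) free-text medication entries into the WHO Anatomical
    Therapeutic Chemical (ATC) classification. Raw entries are
    transliterated, tokenized and stoplist-filtered, chemotherapy regimen
    acronyms and abbreviations are expanded through a regimens-and-
    abbreviations dictionary, and the resulting tokens are looked up in an
    ATC dictionary. Multi-code conflicts are resolved by preferring
    antineoplastic (chapter L) codes, and the output is a structured table
    separating antineoplastic medication, additional medication, uncoded
    medication names, study indicators and supplementary therapy
    information. Includes an evaluation module implementing a three-way
    outcome taxonomy against gold annotations, and a synthetic-fixture
    generator producing structurally faithful toy dictionaries and
    gold-labelled corpora for closed-loop testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
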