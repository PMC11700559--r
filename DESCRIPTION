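Package: sigdose
Title: Rule-Based Daily Dosage Extraction from Free-Text Prescription Sigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministically converts free-text prescription signatures
    (sigs, e.g. "take one tablet twice daily") into structured daily-dosage
    period objects using lexical normalization and regular-expression
    extraction, including titration splitting on "then"/"increase to",
    q-notation interval parsing, parenthetical strength handling, PRN
    semantics and an uncertainty flag for unconsumed numerals. Ships the
    matching evaluation framework (sig-level exact-match confusion counts,
    PPV/sensitivity/F1, subgroup tables, paired permutation test) and a
    seeded synthetic generator of gold-annotated sigs so the whole pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
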