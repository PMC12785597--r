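Package: ampliScreen
Title: In Silico PCR Screening of Primer Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Virtual PCR for species-authentication primer panels. Locates
    approximate primer binding sites on candidate template sequences under
    IUPAC-aware matching on both strands, pairs converging sites into
    predicted amplicons with product length and sequence, and profiles
    primer-template mismatches with 3'-terminal emphasis. An amplifiability
    rule (two or more mismatches within the 3'-terminal five bases of either
    primer, or more than three mismatches across a primer) yields
    per-template verdicts and cross-species panel reports with optional
    confusion summaries. A seeded synthetic-template generator plants primer
    binding sites with controlled mismatch placement and records ground
    truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
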