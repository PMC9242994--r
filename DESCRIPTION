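Package: circtrans
Title: Screening and Proteogenomic Analysis of Circular RNA Translation
Version: 0.9.0
Authors@R:
    person("circtrans", "developers", email = "circtrans@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cap-independent translation of circular RNAs
    (circRNAs). Implements the hexamer enrichment statistic for FACS reporter
    screens that discover IRES-like short elements, hexamer-set frequency
    comparisons across transcript classes with Kolmogorov-Smirnov tests and
    positional profiles, an open-reading-frame caller for circular sequences
    that detects rolling-circle ORFs, and a back-splice-junction peptide
    database builder with the sequential peptide-spectrum-match filter
    cascade used to identify circRNA-coded proteins in public proteomes.
    Ships ground-truthed synthetic-data generators so every stage is testable
    offline, plus a small pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
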