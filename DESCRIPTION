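Package: laolink
Title: Deterministic, Probabilistic and Hybrid Patient Matching for Lao-Script Health Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deduplicating child health registries recorded in Lao
    script or Latin transliteration. Provides Lao-aware text normalization, a
    rule-table deterministic matcher with blocking on date of birth, sex and
    village, a from-scratch Fellegi-Sunter probabilistic matcher with
    Jaro-Winkler comparison levels and expectation-maximization parameter
    estimation, a hybrid combiner that applies probabilistic matching to the
    deterministic residual, record-level evaluation against a gold-standard
    partition, and a calibrated synthetic registry generator with known truth
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
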