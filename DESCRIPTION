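Package: adaptest
Title: Define, Administer and Score XML-Described Psychometric Instruments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An engine for software-independent psychometric instruments
    described in a compact XML dialect: policies, localized instructions and
    practice items, ordered test items, shared response categories with an
    arithmetic response-mapping mini-language, and pluggable score
    computation.  Scoring is backed by an item response theory core
    (two-parameter logistic and graded response models, expected a
    posteriori trait estimation with quadrature, Fisher information,
    response simulation), by exhaustive pre-computed lookup tables over all
    response patterns, and by a pre-computed binary decision tree for
    fixed-length computerized adaptive testing.  A session engine enforces
    instrument policies, records and persists respondent sessions with
    timestamped backups, exports a single analysis-ready table, and queues
    server submissions with at-least-once delivery.  Fixture generators
    produce synthetic instruments, item banks and simulated cohorts, and a
    command-line interface binds the pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
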