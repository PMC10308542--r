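Package: ftrclassify
Title: Future Time Reference Classification and Temporal Cognition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people talk about the future and how that
    relates to temporal cognition. Provides a two-stage classification system
    for sentence-level time reference: a trainable classifier estimating
    whether a sentence refers to the future (FTR) or past (PTR), and a
    deterministic closed-vocabulary classifier assigning future-referring
    sentences to tense and modal semantic categories (future/present tense,
    low/high certainty, deontic, bouletic, irrealis) with negation and
    mixed-modal exclusions. Also includes a rule-based temporal expression
    tagger with a sentence time-horizon statistic, Kirby-style hyperbolic
    delay-discounting estimation from intertemporal choice batteries, DASS-21
    scoring, a two-equation bootstrap mediation model with
    indirect/direct/total effect decomposition, and seeded synthetic-data
    generators so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
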