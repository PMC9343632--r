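Package: thoughtrec
Title: Conversational Thought Recording with Tiered Feedback and Trial Machinery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running and evaluating a conversational agent that
    guides users through cognitive-therapy thought records. Provides a
    deterministic dialogue engine with the downward-arrow technique, a
    pluggable nine-schema utterance scorer with a transparent bag-of-words
    baseline, three tiers of post-record feedback (acknowledgment,
    step-count chart, schema spider chart), covariate-adaptive minimization
    randomization, questionnaire scoring with reliability and Box-Cox
    utilities, a Baron-Kenny mediation and moderation analysis pipeline for
    a Poisson count outcome and a ceiling-skewed engagement outcome, and a
    bias-corrected bootstrap power simulation for the three-arm mediation
    design. A synthetic-participant simulator generates transcripts,
    labelled corpora, Likert data with target reliability, and full study
    tables so every component can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
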