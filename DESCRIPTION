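Package: distractlab
Title: Distractor Analysis and Option-Reduction Simulation for
    Multiple-Choice Examinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical-test-theory tools for analysing the incorrect options
    (distractors) of one-best-answer multiple-choice examinations. Detects
    rarely selected ("non-functional") distractors at configurable selection
    thresholds, quantifies how strongly each distractor attracts
    low-performing candidates (delta-medians), simulates the removal of the
    least and second-least chosen distractors under extreme assumptions about
    candidate behaviour (random reallocation versus switching to the correct
    answer), recomputes difficulty, discrimination, Cronbach's alpha and
    Spearman-Brown standardized reliability, and evaluates how well expert
    least-plausibility ratings recover non-functional distractors. Includes a
    nominal-response simulator that generates realistic synthetic exams and
    expert ratings so every analysis can be exercised without confidential
    examination data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
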