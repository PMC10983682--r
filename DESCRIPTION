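Package: spictminer
Title: Rule-Based SPICT-LIS Screening of Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based text mining of electronic doctor's notes to flag
    hospitalized cancer patients who may benefit from palliative care,
    following the six general indicators of the Supportive and Palliative
    Care Indicators Tool for Low-Income Settings (SPICT-LIS). Provides a
    replaceable term dictionary with nested strict and relaxed keyword
    profiles, dictionary-based longest-match tokenization for mixed
    segmented/unsegmented scripts, window-based negation detection,
    cohort inclusion/exclusion filters (admission-before-diagnosis,
    short notes, non-malignant ICD-O behavior), inter-rater agreement
    statistics (percent agreement, Cohen's kappa with confidence
    interval and interpretation bands), prevalence and two-by-two
    association measures, and a seeded synthetic-cohort generator with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
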