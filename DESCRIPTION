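Package: cogehr
Title: Rule-Based Detection of Documented Cognitive Impairments in
    Clinical Notes and Healthcare Utilization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying documented cognitive
    impairments among patients with schizophrenia in electronic health
    record (EHR) and linked administrative-claims data.  Provides a
    five-domain lexicon of cognitive-impairment phrases compiled to
    word-boundary regular expressions, a clinical-note extractor with
    sentence segmentation and sentence-level context exclusion (negation,
    question, goal, family history), a calibrated synthetic EHR + claims
    generator with gold labels, retrospective cohort construction with
    index dates and continuous-enrollment checks, precision/recall/F1
    evaluation against gold labels, and per-patient-per-year healthcare
    resource utilization summaries with negative binomial regression and
    marginally standardized adjusted rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    stringi,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
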