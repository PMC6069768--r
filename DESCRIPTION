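Package: nyhaclass
Title: Identify NYHA Functional Class in Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for extracting New York Heart Association (NYHA) functional
    class (I-IV) from free-text clinical notes and structured diagnosis-code
    descriptions. Provides a rule-based extractor built on a trigger lexicon and
    a bounded character window, a mapper from custom diagnosis-code labels to
    NYHA classes, construction of a labelled reference corpus by patient/date
    matching against coded encounters, a bag-of-words / n-gram text
    classification pipeline (support vector machine, logistic regression,
    random forest) with stratified cross-validation, macro-averaged multi-class
    evaluation reports, and a seeded synthetic EHR generator for end-to-end
    testing without real patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    yaml,
    withr,
    e1071,
    glmnet,
    ranger,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
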