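Package: rsmcat
Title: Computerized Adaptive Testing for Rasch Rating Scale Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computerized adaptive testing (CAT) engine for polytomous
    questionnaire items under the Rasch rating scale model. Provides anchored
    item-bank handling (with the 18-item inpatient perception questionnaire,
    IPQ-18, as a packaged bank), category probabilities and item information,
    maximum-likelihood person measurement by Newton-Raphson iteration,
    maximum-information item selection with standard-error and minimum-length
    stop rules, infit/outfit person-fit statistics, and a simulation framework
    that quantifies the efficiency gain and measurement-precision parity of
    adaptive testing against full-length nonadaptive administration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
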