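Package: aphasim
Title: Active Inference Simulation of Recovery Patterns in Bilingual Aphasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active inference (POMDP) machinery and a generative
    model of three bilingual language tasks (picture naming, word repetition,
    word translation), together with an in-silico precision lesion on the
    likelihood mapping and a daily testing paradigm. The lesioned synthetic
    subject reproduces the alternate-antagonism and paradoxical-translation
    recovery pattern reported for bilingual aphasic patients, against a
    matched-seed control subject. Includes exhaustive-enumeration oracles for
    testing the variational engine, a day-indexed precision schedule, study
    scoring, a recovery-pattern classifier, and a configuration-driven command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
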