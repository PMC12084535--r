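Package: edsepsis
Title: Uncertainty-Gated Early Sepsis Alerting with Note-Based Differential Diagnosis
Version: 0.1.0
Authors@R:
    person("ED Sepsis Analytics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for building and evaluating hourly early-sepsis alerting
    pipelines in the emergency department. A continuous sepsis risk score is
    gated by two decision thresholds: high scores fire an alert directly,
    while scores in an intermediate high-uncertainty band are adjudicated by
    a note-based differential-diagnosis step. Clinical signs are extracted
    from free-text notes by a pluggable retrieval-augmented extractor (a
    deterministic phrase-matching mock is the tested path), fed into a
    naive-Bayes posterior over severe sepsis and 18 sepsis-mimics, and an
    alert fires only when severe sepsis ranks among the top differentials
    with a suspicion of bacterial infection. The package also provides
    Sepsis-3 encounter phenotyping (suspicion-of-infection order windows plus
    an acute SOFA rise), a synthetic emergency-department cohort generator
    for end-to-end testing, alarm silencing, encounter-level
    sensitivity/PPV/F1, and false-alarms-per-patient-hour accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
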