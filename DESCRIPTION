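Package: maladapt
Title: Multiparameter Diagnosis of Maladaptation to Exercise Training Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multidimensional diagnostic model for detecting
    maladaptation (non-functional overreaching) to high-intensity interval
    training: individual baselines over normal-load training phases,
    group-derived directional cut-offs (half the group mean difference
    between maladaptive and normal training load), binary positive scoring
    of five easily accessible parameters (POMS fatigue, session maximal
    heart rate, end-of-session blood glucose and lactate, mean RPE), and a
    3-of-5 classification rule.  Also provides the derived session metrics
    the model consumes (rolling-window peaks, heart-rate recovery, Brouwer
    substrate oxidation, mood-state indices), a constrained synthetic-cohort
    generator that reproduces the published per-parameter and joint score
    distributions of an 11-subject, 6-phase cohort, and a CSV pipeline with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
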