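Package: fbidose
Title: Adaptive Duration Finding for Cardio-Visual Full-Body-Illusion Pain
    Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for adaptive duration ('dose') finding in extended-reality
    cardio-visual full-body-illusion interventions for fibromyalgia. Implements
    the preset cohort escalation/de-escalation rule engine with full-trial
    replay, a synthetic-participant trial simulator for operating-characteristic
    studies, the dose-response analysis stack (polynomial regression with
    nested-model likelihood-ratio tests, paired t-tests with Cohen's d,
    correlation, ANCOVA with Bonferroni-adjusted estimated marginal means),
    questionnaire scoring (ACR 2016 fibromyalgia criteria, small-fibre
    neuropathy and pain-catastrophizing scales), and a real-time ECG-to-visual
    synchrony algorithm (zero-phase Butterworth filtering, threshold R-peak
    detection, fixed-timestep opacity scheduling, flash-latency auditing).
    Ships the per-participant dataset of the original 20-participant,
    seven-cohort duration-finding study so every reported result can be
    recomputed offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
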