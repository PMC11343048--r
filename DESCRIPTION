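Package: awcsim
Title: Simulation and Evaluation of Two-Stage AED Shock Advisory Analysis
    During CPR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying automated external defibrillator (AED)
    shock advisory protocols that analyse the ECG rhythm while chest
    compressions are ongoing.  Implements the Analyze Whilst Compressing
    (AWC) two-stage decision state machine (a 16 s rhythm analysis during
    compressions, gated at one minute into the CPR phase, followed by a
    5 s confirmation analysis on paused compressions), a seeded generator
    of synthetic ECG rhythms, compression artifact and transthoracic
    impedance, an out-of-hospital cardiac arrest intervention simulator
    with an exponential refibrillation model, reference and oracle shock
    advisory classifiers, and a performance evaluator producing clustered
    sensitivity/specificity estimates with one-sided 90% lower confidence
    limits, confirmation-rate and hands-off-time metrics.  Published
    per-stage decision-count tables from a clinical AWC evaluation are
    packaged as fixtures so the pooled performance arithmetic can be
    reproduced exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
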