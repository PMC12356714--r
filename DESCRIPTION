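Package: mslt
Title: Simulation and Analysis of a Motor Sequence Learning Task with Skip Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to generate, simulate, and analyze a serial-response motor
    sequence learning task used to study habit formation. Builds trial-exact
    task plans (pseudo-random baseline blocks, fixed 12-item sequence blocks,
    and test blocks with intermittent skip events), implements the adaptive
    response-deadline staircase that paces the task, provides a generative
    synthetic-participant model producing practice-dependent speed-ups,
    errors, and anticipatory action slips, and scores trial-level event logs
    into correct-only median reaction times, error rates, action-slip counts,
    reliable change indices, within-subject repeated-measures ANOVA tables
    with Greenhouse-Geisser correction and partial eta squared, and
    speed-accuracy correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
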