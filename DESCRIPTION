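Package: riskcontext
Title: Temporal-Context Effects in Risky Choice with Arousal Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how temporal context shapes risky monetary
    decision-making at immediate (previous outcome), neighborhood (run-level
    shifts in expected value) and global (cumulative earnings relative to
    expectations) timescales. Generates temporally structured gain-only choice
    sets organized into runs of shared expected value separated by signed
    shifts, simulates synthetic cohorts of context-sensitive choosers together
    with event-locked skin-conductance traces, scores skin-conductance
    responses by windowed trough-to-peak amplitude with square-root/maximum
    normalization, builds normalized per-trial context regressors, estimates
    the two-step offset mixed-effects model suite built on 'lme4', and runs
    simulation-based power analyses with exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
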