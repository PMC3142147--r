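Package: phosphene
Title: Adaptive Estimation of TMS Phosphene Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating transcranial magnetic stimulation (TMS)
    phosphene thresholds without stimulator hardware. Implements a Psi
    Bayesian adaptive staircase that maintains a posterior over Weibull
    psychometric-function parameters and selects each pulse intensity by
    one-step-ahead expected-entropy minimization, terminating after a fixed
    30 trials; a modified binary search (MOBS) comparator staircase with
    boundary stacks and reversal-based termination; and a method of constant
    stimuli (MOCS) workflow with maximum-likelihood Weibull fitting and
    parametric-bootstrap threshold errors. Simulated yes/no and
    two-alternative forced-choice observers, a mock pulse-delivery device
    with safety timing, session logging with deterministic replay, and an
    in-silico validation study comparing the procedures are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
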