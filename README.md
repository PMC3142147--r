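# phosphene

Adaptive estimation of TMS phosphene thresholds, without stimulator
hardware or human participants.

## The problem

Transcranial magnetic stimulation (TMS) of the occipital cortex elicits
phosphenes — illusory flashes of light — once the pulse intensity exceeds an
individual's **phosphene threshold (PT)**, the intensity (in % of the
stimulator's maximum output) that induces phosphenes on a criterion
proportion of trials. The PT calibrates TMS dose for visual-cortex studies,
so it needs to be estimated accurately, reliably and quickly from a short
sequence of yes/no "seen / not seen" reports.

This package implements and compares three estimation procedures entirely
in silico:

- **REPT** (rapid estimation of phosphene thresholds): a Ψ Bayesian
  adaptive staircase. It maintains a discretized posterior over the
  position α and slope β of a lapse-corrected Weibull psychometric
  function

  ψ(x) = γ + (1 − γ − λ)(1 − e^−(x/α)^β),

  with the guess rate γ = 0 for yes/no detection and the lapse rate fixed
  at λ = 0.04. Each pulse intensity is chosen to minimize the expected
  Shannon entropy of the posterior after the upcoming response, and the run
  always terminates after 30 trials. The reported threshold is the
  intensity at which the fitted lapse-corrected curve reaches 60% accuracy
  (the lapse-corrected analogue of the 63% Weibull convention); a post-hoc
  50% threshold is also computed.
- **MOBS** (modified binary search): a bisection staircase with boundary
  stacks over the 1–100% range, terminating after six response reversals.
- **MOCS** (method of constant stimuli): seven fixed levels presented 20–30
  times each in random order, fitted by maximum likelihood with
  parametric-bootstrap threshold errors; the conventional proxy for ground
  truth.

Simulated observers (Bernoulli responses from a lapse-corrected Weibull,
including a 2AFC variant with γ = 0.5), a mock pulse-delivery device with a
safety-interval gate, timestamped session logs with deterministic replay,
and a panel-level validation study tie the pieces together.

## Worked example

```r
library(phosphene)

# a simulated observer with true alpha = 60, beta = 10, 4% lapses
obs <- sim_observer(weibull_params(alpha = 60, beta = 10, lapse = 0.04), seed = 7)
res <- run_rept(obs)
res
#> REPT staircase result (30 trials)
#>   threshold (60% accuracy): 66.53
#>   alpha estimate: 66.84   beta estimate: 4.20
#>   post-hoc 50% threshold: 62.13
```

The observer's true 60% point is 59.9, so this single 30-trial run lands
within about 6.6 intensity units; across seeds the estimates are unbiased
with an SD near 3 units (run-to-run spread is what the validation study
quantifies). The slope estimate is loose by design — 30 trials pin down the
threshold, not the slope. The comparator staircase and the MOCS ground
truth for the same observer:

```r
run_mobs(sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 7))
#> MOBS staircase result: threshold 54 after 13 trials (6 reversals)

design <- design_mocs(round(res$threshold), seed = 1)    # 7 levels, 25 reps
dat <- run_mocs(sim_observer(weibull_params(60, 10, lapse = 0.04), seed = 8), design)
fit <- bootstrap_threshold_se(fit_weibull_ml(dat), n_boot = 400, seed = 1)
fit
#> MOCS maximum-likelihood Weibull fit
#>   alpha = 57.87, beta = 12.58 (guess 0, lapse 0.04 fixed)
#>   log-likelihood = -61.95
#>   threshold at 60%: 57.78   at 50%: 56.47
#>   bootstrap SE: 0.90 (60%), 0.91 (50%) [400 resamples]
```

Results carry tidy tibbles: `tidy()` returns trial-by-trial histories or
parameter tables, `glance()` one-row summaries, and `autoplot()` staircase
traces, fitted psychometric functions and comparison scatterplots. A full
panel comparison (`n` observers × 4 REPT + 4 MOBS + 1 MOCS each):

```r
report <- run_comparison(observer_panel(10, seed = 42), seed = 1)
glance(report)     # panel means of |error|, run-to-run SD, trial counts
autoplot(report)
```

A thin command-line front end lives at `inst/cli/phosphene.R`
(`rept run|replay`, `mobs run`, `mocs run|fit`, `validate panel`).

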