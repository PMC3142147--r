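---
title: "Methods: adaptive phosphene-threshold estimation in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive phosphene-threshold estimation in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphene)
```

## The psychometric model

Every procedure in this package rests on the lapse-corrected Weibull
psychometric function on the linear intensity axis,

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\left(1 - e^{-(x/\alpha)^\beta}\right),$$

with position $\alpha$ (the intensity at which the lapse-free, guess-free
curve reaches $1 - e^{-1} \approx 63\%$ detection), slope $\beta$, guess
rate $\gamma$ and lapse rate $\lambda$. The Weibull is the standard choice
for detection-type psychometric data; no alternative sigmoids are offered.

Two conventions matter and are fixed throughout:

- **Yes/no phosphene detection uses $\gamma = 0$.** Participants in
  phosphene work are instructed to respond "no" when unsure, so the false
  alarm floor is taken as zero. The 2AFC validation observer instead uses
  $\gamma = 0.5$.
- **$\lambda = 0.04$ is fixed, not estimated.** A 4%-of-trials lapse
  allowance compresses the upper asymptote to 0.96. With this correction,
  the staircase's reported threshold is defined as the *exact* 60% crossing
  of the fitted curve, `threshold_at_accuracy(0.60, fit)`. Note the
  near-miss this convention resolves: $\psi(\alpha)$ with $\gamma = 0,
  \lambda = 0.04$ is $0.96(1 - e^{-1}) \approx 60.7\%$, so "the threshold
  corresponds to 60% accuracy" is ambiguous between reporting $\alpha$
  itself ($\approx 61\%$) and the exact crossing. This package reports the
  exact 60% crossing, which makes the 60% property hold by construction;
  the two differ by a fraction of an intensity unit at realistic slopes.

The inversion is closed-form,
$x = \alpha\left[-\log\left(1 - \frac{p-\gamma}{1-\gamma-\lambda}\right)\right]^{1/\beta}$,
and is exercised in tests against a bisection root-finder and as a
round-trip identity at tolerance $10^{-9}$.

## The Ψ staircase (REPT)

The staircase maintains a discretized posterior over $(\alpha, \beta)$
pairs. Defaults, chosen once for the phosphene setting (the stimulator
accepts integer percent of maximum output):

- $\alpha$ grid: $1, 2, \dots, 100$ (% of maximum output). Covers the full
  deliverable range so ceiling/floor observers push mass to the grid edge
  rather than off it.
- $\beta$ grid: 10 log-spaced values in $[0.5, 20]$. Log spacing reflects
  that slope uncertainty is multiplicative; the range brackets shallow
  through steep psychometric functions.
- stimulus grid: integers $1..100$.
- prior: uniform over the $(\alpha, \beta)$ grid — the least-informative
  choice on a bounded grid, and the natural default when no population
  prior is published.

All three axes are overridable (the 2AFC validation below uses log-spaced
contrast axes).

On each trial the candidate intensity $x$ is scored by its one-step-ahead
expected posterior entropy

$$E[H](x) = P(r{=}1 \mid x)\,H_1 + P(r{=}0 \mid x)\,H_0,$$

where $P(r{=}1\mid x) = \sum_{\alpha,\beta} p_t(\alpha,\beta)\,
\psi_{\alpha\beta}(x)$ and $H_r$ is the Shannon entropy (nats — the argmin
is base-invariant) of the Bayes-updated posterior under outcome $r$. The
delivered intensity is the argmin; **ties break toward the lowest
intensity**, a deliberate comfort-first rule that must be fixed because it
affects exact trial sequences. The posterior is renormalized after every
update (tested to $10^{-10}$), and the staircase itself is fully
deterministic: randomness enters only through the observer.

A run is always exactly 30 trials. Fixed-length termination trades a few
possibly-redundant trials for complete predictability of session duration;
dynamic stopping rules are deliberately out of scope. The point estimate is
the **marginal posterior mean** of $\alpha$ and $\beta$ — a posterior mode
would inherit grid-quantization noise — converted to the 60% crossing and
clamped to the stimulus range. Estimates are reported continuous; only
delivered intensities are integers.

Implementation notes: the likelihood table is precomputed over the full
$(\alpha,\beta) \times x$ grid; $0\log 0$ is evaluated as 0 (likelihoods
can underflow to exactly zero at extreme grid corners, e.g. $x \ll
\alpha$ at $\beta = 20$); the expected-entropy computation is vectorized
over candidates but is verified in tests against a naive double-loop
oracle at $10^{-12}$, and the argmin against exhaustive search.

## MOBS

The modified binary search is implemented as the cited two-stack variant —
the field's spreadsheet implementations are not published, so this is
"MOBS as cited, not as copied":

- boundary stacks initialized at 1 and 100; the test value is the integer
  midpoint of the stack tops, **rounding half up** (so the first trial is
  at 51);
- "seen" pushes the tested value as a new upper boundary, "not seen" as a
  new lower boundary;
- after two consecutive identical responses the *opposite* stack pops one
  level (never below its initial value) — the retreat rule that lets MOBS
  recover from a response error;
- termination at the sixth reversal (change of response category between
  consecutive trials; the first trial can never be one), with a hard
  100-trial safety cap for pathological responders;
- the estimate is the pending midpoint at termination — the level the
  bisection has converged on, a 50%-point estimate.

The retreat rule and final-estimate formula are genuinely open choices (a
mean of the last reversal intensities is a common alternative readout);
both are documented here because they change exact trial sequences. One
consequence of integer midpoints: mirror symmetry of the update rules about
intensity 50.5 is exact only in real arithmetic; the integer implementation
tracks its mirrored run to within a few units (tested against an unrounded
reference implementation).

## MOCS

`design_mocs()` places 7 integer levels at 5% spacing centered on a pilot
threshold (staircase estimates are the intended pilot), presented 25 times
each (20–30 is the conventional range) in a seeded random permutation. A
window overhanging the 1–100% range is slid back inside it so all levels
stay distinct; a design that cannot fit 6 distinct levels is refused. At
realistic slopes ($\beta \approx 8$–12 around $\alpha \approx 60$) the
$\pm 15\%$ window spans near-0% to near-100% expected detection.

`fit_weibull_ml()` maximizes the binomial log-likelihood
$\sum_i k_i \log \psi(x_i) + (n_i - k_i)\log(1 - \psi(x_i))$ over
$(\log\alpha, \log\beta)$ with Nelder–Mead from 5 starting points spread
over the sampled intensity range — the likelihood is flat in $\beta$ when
the data pin the curve poorly, and multistart guards against those
plateaus. $\gamma = 0$ and $\lambda = 0.04$ are held fixed for consistency
with the staircase (fitting conventions differ on this; fixing keeps the
60%-readout comparable across procedures). Predicted probabilities are
clamped to $[10^{-10}, 1-10^{-10}]$ inside the likelihood; all-seen or
all-unseen datasets are refused as non-identifiable. Tests check the fit
against a dense grid-search oracle (within one grid cell) and
near-noiseless recovery within 2%.

`bootstrap_threshold_se()` is a parametric bootstrap: simulate per-level
binomial counts from the fitted curve, refit (2 starts — cheaper, and the
resamples start near the truth), report the SD of the refitted 60% and 50%
thresholds over 400 resamples by default. More than 20% failed refits
raises an instability error rather than a silently optimistic SE.

## Simulated observers

`sim_observer()` draws i.i.d. Bernoulli responses from $\psi(x)$ with a
private RNG stream (identical seed + stimulus sequence gives an identical
response stream, independent of the global RNG). `observer_panel()` draws
$\alpha \sim U(40, 80)$ and $\beta \sim \exp(U(\log 4, \log 16))$ with
$\lambda = 0.04, \gamma = 0$ — plausible brackets for per-participant
phosphene curves, documented as a choice rather than extracted values.

What the simulator deliberately omits: inter-trial dependence, criterion
drift, dark-adaptation and arousal effects, coil-position drift. Passing
tests therefore demonstrate the *procedures'* statistical behaviour under a
stationary observer, not robustness to the nonstationarities of real
sessions.

## Sessions, timing and replay

The staircases talk to a pulse-delivery contract (set intensity, arm,
trigger) with a mock implementation; a driver for a real serial-controlled
stimulator is an extension point, not implemented here. The mock enforces a
minimum inter-pulse interval (default 2.5 s; slow mode 6 s) on a virtual
clock and refuses early pulses. Sessions pace conservatively: the full
minimum interval elapses *after each response* (default response latency
0.35 s), so default 30-trial runs last about 83 s — an average stimulation
frequency of ≈ 0.36 Hz, and ≈ 0.16 Hz in slow mode. Session logs
(CSV trial table + JSON config/result block) replay deterministically:
`replay_session()` re-runs the logged procedure on the logged responses and
errors on any divergence in intensity sequence or threshold, which doubles
as a tamper/version check.

## The validation study

`run_comparison()` mirrors the staircase-vs-ground-truth comparison logic:
per observer, 4 REPT and 4 MOBS runs plus one MOCS session (its design
centered on the mean REPT estimate, as pilot-informed MOCS is run in
practice), all seeded. Accuracy is the absolute difference of each
procedure's mean-of-4 from the observer's *analytic* 60% point — available
in silico, and the cleaner truth; the MOCS estimate is reported alongside
as the proxy truth, with REPT matched to the MOCS 60% threshold and MOBS
to the 50% threshold (MOBS converges on the 50% point). Reliability is the
SD over the 4 runs; durations are reported as trial counts, since
wall-clock depends on hardware pacing. Panel-level inferential statistics
are out of scope — the direction of effect (REPT more accurate and more
reliable than MOBS over a majority of seeded panels) is the tested
property, not any human-data magnitude.

## Problem sizes used in the test suite

Simulation-backed tests use sizes chosen to make their statistical checks
stable at comfortable margins: 50–60 runs for entropy-descent and
recovery-bias checks, 200 observers for the median-recovery property
(median |error| ≤ 3 intensity units), 200 seeded 30-trial 2AFC staircases
for the precision check (SD of estimates ≤ 2 dB, on a log-spaced contrast
axis with a $\gamma = 0.5$, $\lambda = 0.01$, $\alpha = 0.1$, $\beta = 3$
observer), 5 seeded 5-observer panels for the direction-of-effect check,
and 60–100 bootstrap resamples where a full 400 would add nothing to the
property under test.

## Known limitations

- The lapse rate is fixed; a mis-specified $\lambda$ biases the 60%
  readout slightly (the cost of not spending trials estimating it).
- The slope estimate after 30 trials is imprecise by design; the post-hoc
  50% threshold inherits that imprecision and the 60% readout is the
  recommended quantity.
- Grid-bounded inference: observers with true thresholds at or beyond the
  grid edge are clamped, and estimates there are biased inward.
- MOBS heuristics (retreat rule, estimate readout) follow the cited
  two-stack variant; other spreadsheet implementations in circulation may
  differ in detail.
- The simulated-observer panel is a stationarity idealization; see above.
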