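---
title: "Modeling temporal-context effects in risky choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temporal-context effects in risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcontext)
```

## The scientific question

In a fully instructed risky-choice task, each trial offers a gamble (a 50/50
chance of a positive dollar amount or $0) against a guaranteed amount. If
choices depended only on the explicitly stated values and probabilities,
recent events would be irrelevant. The question this package's pipeline
addresses is whether and how *temporal context* nevertheless shapes
risk-taking, at three timescales:

* **immediate** — the outcome received on the previous trial;
* **neighborhood** — runs of consecutive trials sharing a mean expected
  value (an "EV level"), separated by abrupt signed shifts;
* **global** — cumulative earnings, evaluated against a linear expectation
  of how earnings should grow over the task.

A parallel question is whether physiological arousal, measured as
skin-conductance responses (SCRs), tracks any of these timescales.

Because the interesting estimands are coefficients of a hierarchical
logistic model, the package's primary verification surface is *parameter
recovery on synthetic cohorts*: simulate subjects whose choices follow a
known context-sensitive model, run the full estimation pipeline, and check
that the generative coefficients are recovered.

## The structured task

`make_choice_set()` generates gain-only choice sets with deliberate
temporal structure: 240 trials (a 171-trial variant is available through
`n_trials`) partitioned into 9–10 runs of 9–36 trials. All trials in a run
share an EV level $L$; safe amounts are $L + u$ and risky gains
$2(L + u')$ with independent uniform noise $u, u' \in [-2, 2]$ dollars,
rounded to cents, so the risky gain is roughly double the safe amount and
both options have (up to noise) the run's expected value. Between runs the
EV level shifts by a signed amount with magnitude $5–$15 in $1.25
increments.

Design choices worth recording:

* **Run lengths are sampled uniformly over all bounded integer
  compositions** of the trial count, using an exact dynamic-programming
  count table rather than rejection sampling. This makes every admissible
  run-length profile equally likely, is deterministic given the seed, and
  costs milliseconds (rejection sampling at these bounds wastes thousands
  of draws). Infeasible configurations (e.g. 9 runs of at least 9 trials
  cannot fit in 60 trials) are reported as configuration errors naming the
  violated bound.
* **EV levels live on a quarter-dollar grid** inside $[\$2.25, \$33]$ so
  that $1.25-increment shifts keep levels on-grid and realized amounts stay
  inside $[\$0.25, \$35]$ (safe) and $[\$0.50, \$70]$ (risky) under the
  ±$2 noise. From any level inside these bounds at least one signed shift
  is admissible, so the level walk cannot dead-end; the sampler still
  carries a bounded re-draw guard for non-default configurations.
* **Trial timing** (2 s option display, up to 2 s response, 0.5 s
  interstimulus gap, 1 s outcome, 1.5–4.5 s intertrial interval plus the
  unused response time) is generated only because SCR synthesis needs
  event onsets; behavioral modeling ignores it.

## The generative cohort model

`simulate_cohort()` draws, per subject, a coefficient vector around
population means and simulates choices sequentially through
$P(\text{gamble}_t) = \operatorname{logit}^{-1}(\eta_t)$ with

$$\eta_t = \beta_{rg}\,rg_t + \beta_{s}\,s_t + \beta_{m}\,m_t
  + \beta_{o}\,o_{t-1} + \beta_{+}\,\delta^{+}_t + \beta_{-}\,\delta^{-}_t
  + \beta_{e}\,e_t + \beta_{x}\,x_t + \beta_{eo}\,e_t\,o_{t-1} + b_0,$$

where $rg, s, m$ are the normalized risky-gain, safe and EV-level amounts,
$o_{t-1}$ the normalized previous outcome, $\delta^{\pm}$ the positive and
negative parts of the normalized EV shift (nonzero only on a run's first
trial), $e_t$ normalized cumulative earnings *before* trial $t$, $x_t$ the
normalized linear expectation, and $b_0$ a subject random intercept.
Outcomes are stochastic (a taken gamble pays its risky gain with
probability 0.5) and feed forward into earnings, so context regressors use
the *realized* history — the same information set the estimation stage
sees.

Population defaults are the fitted estimates of the reference analysis
(current-trial model: 30.88, −13.18, −49.51; full context model: −0.7,
5.3, −0.37, 0.37, −0.26, and 1.3 for the earnings-by-outcome interaction).
Three choices were genuinely open:

* **Between-subject heterogeneity.** The analysis models posit random
  slopes only for the risky-gain and safe amounts (plus a random intercept
  in the context models), so only those coefficients vary across subjects
  by default. Their SDs use an SE·√N heuristic (2.9·√62 ≈ 22.8 and
  5.19·√62 ≈ 40.9) since no generative SDs are reported. A consequence
  worth knowing: with slope SDs this large, a substantial minority of
  synthetic subjects are near-deterministic (all-safe or all-gamble)
  choosers. At the full cohort scale (60 × 240) recovery is unaffected;
  small machinery tests use narrower SDs so that every subject is
  informative. All SDs are config-overridable.
* **Context coefficients are population-homogeneous** (SD 0), because the
  context models estimate them as pure fixed effects; the random intercept
  SD defaults to 0.3.
* **Missed trials** are injected uniformly at random at a 0.5% rate
  (echoing the reported 120 missed of ~14.9k trials); no structure in
  missingness is modeled. Where the previous outcome is undefined (trial 1
  or after a miss), the generative model simply omits the
  previous-outcome terms, matching the estimation-side exclusion of those
  trials.

## Normalization

The reference analysis reports unitless-looking coefficients without
stating its regressor scaling. Two constants reproduce the printed
arithmetic and are therefore the defaults, flagged as a reconstruction:

* `money_scale` divides every dollar-valued regressor and defaults to the
  dataset's maximum outcome (≈$68–70 for this design). Reverse-engineering
  the printed effect translations pins this down:
  $100\,[\operatorname{logit}^{-1}(0) - \operatorname{logit}^{-1}(-0.15 \cdot 68/68)] = 3.7$
  percentage points, and
  $100\,[\operatorname{logit}^{-1}(4.8 \cdot 15/68) - 0.5] = 24.2$.
* `earnings_scale` divides cumulative earnings and the linear expectation
  and defaults to the expected total earnings at the final trial
  (mean EV level × trial count), making both regressors O(1) — consistent
  with the printed coefficient magnitudes — and making the normalized
  expectation end at exactly 1.

Cumulative earnings at trial $t$ sum outcomes on trials $1..t-1$; the
current trial's outcome is excluded because it is not in the decision's
information set. The linear expectation is a straight line,
$x_t = t \cdot \overline{L}$, whose slope depends only on the task-level
mean EV, not on run ordering.

## The two-step offset procedure

Because all trials within a run share an EV level, current-trial values
and context regressors are collinear by construction. The pipeline
therefore estimates in two steps:

1. **Model 1**: `choice ~ 0 + riskygain + safe + magnitude` with
   correlated subject random slopes for risky gain and safe, by binomial
   mixed-model maximum likelihood (Laplace approximation).
2. Its linear predictions **before the link function** become a
   per-observation *offset* (coefficient fixed at 1) in every later
   behavioral model, which adds context regressors and a subject random
   intercept.

This gives all variance shared between current-trial values and context to
the current-trial model, so context estimates are *lower bounds* — a
deliberately conservative allocation. Two open details, both
config-exposed:

* The offset includes the subject random-effect modes by default
  (`include_random_offset = TRUE`), matching the default prediction
  behavior of the estimation ecosystem; a flag disables it.
* One model (3c, the shift-by-outcome interaction) is described against
  "model 3" predictions; the pipeline uses the model-1 offset for
  consistency with every other behavioral model, with
  `offset_3c = "model3a"` available as the alternative.

Estimation is delegated to lme4 (`glmer`/`lmer`), the de-facto standard
and the engine the reference analysis itself used; this package owns the
model grammar, the offset plumbing, Wald inference (two-sided normal
reference, consistent with the printed β/SE/p triplets), and the AIC
bookkeeping. An independent 201-node Gauss–Hermite quadrature evaluator
(`gh_marginal_loglik()`, nodes from first-principles Golub–Welsch) serves
as a brute-force oracle for the Laplace marginal likelihood in tests. At
small cluster sizes (tens of Bernoulli trials) the Laplace approximation
is typically within a few hundredths of the exact marginal log-likelihood,
and essentially exact when the fitted random-effect variance is at the
boundary.

## SCR synthesis and scoring

Synthesis (`synthesize_scr_trace()`): each decision and outcome event
contributes a phasic response — a difference-of-exponentials kernel
$h(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ with rise 0.75 s, decay 2 s,
onset latency 1 s, scaled to unit peak (peak ≈ 2.2 s after onset, inside
the scoring window) — superposed on a tonic baseline with optional slow
drift and white noise. Event amplitudes are generated on the normalized
(√/max) scale — outcome events scale with normalized earnings (gain 0.12
per unit), decision events with the normalized positive shift (gain 0.41)
— and converted to µS by inverting the normalization against a
subject-level maximum response (default 0.4 µS, inside the reported
per-subject mean range). Each event is independently zeroed with
probability 0.5, which together with the amplitude floor reproduces the
reported "roughly half of trials respond" regime. The kernel is a modeling
convenience: only its unit peak and its support within the scoring window
matter to the scoring contract, and all parameters are config-exposed.

Scoring (`score_subject()`) follows the standard electrodermal chain:

* a 16-tap windowed-sinc FIR low-pass at 25 Hz (taps renormalized to unit
  DC gain), applied forward with the group delay compensated by an index
  shift — exact to within half a sample for an even tap count, i.e. 2.5 ms
  at 200 samples/s, negligible against a 4 s scoring window;
* 3-sample Blackman smoothing. The conventional symmetric Blackman window
  has zero endpoints, so at width 3 this step is numerically the identity;
  it is retained for procedural fidelity and wider windows behave as
  expected;
* **trough-to-peak amplitude**: the maximum rise from a running minimum
  within the window (0.5–4.5 s after outcome onset; from 0.5 s after
  decision onset until 0.5 s after the response for the decision phase).
  Using the running minimum, not window max − min, means a decline after
  an early peak cannot inflate the score. Scores below 0.02 µS are set to
  0. The score is invariant to any constant baseline shift;
* **√/max normalization** per subject: amplitudes are square-rooted and
  divided by the subject's maximum, so the largest response is exactly 1.
  Note √/max is not idempotent on interior values (√ changes them); its
  fixed points are 0 and the maximum, and ordering is always preserved —
  the tests pin exactly those properties;
* **responder rule**: subjects with a nonzero response on more than 25% of
  events (strict inequality) enter SCR analyses.

What synthetic traces do *not* emulate: habituation of response amplitude
over time, valence-specific responses, movement artifacts, and
superposition bias — closely spaced events ride on each other's tails, so
scored amplitudes of real (and realistically spaced synthetic) events are
biased by neighboring responses. Scoring-accuracy tests therefore use
isolated, noise-free events; pipeline-level tests treat superposition as
part of the measurement noise, as in real recordings.

## Power simulation

`simulate_power()` redraws subject parameters and responses on a fixed
design, re-runs the *full* two-step fit per replicate (the offset depends
on the simulated responses), and counts Wald rejections at level α. The
rejection proportion carries an exact Clopper–Pearson binomial interval;
100 replicates is the default, under which 88 rejections reproduce the
reference interval [79.98%, 93.64%]. Replicate fit failures are excluded
and reported; more than 10% failures aborts.

## Simulation studies and their sizes

The test suite runs two study-scale checks, sized to hold runtime to
minutes while keeping the reference conditions:

* **Parameter recovery**: 20 replicate cohorts at the full study scale
  (60 subjects × 240 trials, default coefficients). Across replicates the
  three reliably nonzero context effects (previous outcome negative,
  positive shift positive, earnings-by-outcome positive) must recover
  their signs in at least 18 of 20, and each context coefficient must fall
  inside its 95% Wald interval in at least 85% of replicates. The
  earnings and expectation main effects are excluded from the *sign* rule:
  their generative values (0.37, −0.26) are smaller than their own
  standard errors at this sample size — the reference analysis itself
  reports them as non-significant in the full context model — so no
  procedure could pin their signs reliably.
* **Null calibration**: 400 replicates on a fixed 12-subject × 120-trial
  design with all context coefficients zero, step 1 fitted with the fast
  penalized-least-squares mode. The Wald test of each context term is
  compared with the nominal 5% level. A structural caveat: the two-step
  offset procedure is conservative by design (step 1 absorbs all shared
  variance, and the offset carries overfitted random-effect modes), so
  rejection rates for the smooth global-timescale terms (earnings,
  expectation) sit *below* nominal — the procedure under-rejects rather
  than over-rejects. The calibration study documents this one-sided
  behavior; it is the statistical price of the lower-bound interpretation
  of context estimates.

## Known limitations

* Context-coefficient estimates inherit the two-step procedure's downward
  bias wherever context and current-trial regressors share variance; they
  are lower bounds, not unbiased estimates.
* The normalization constants are a reconstruction (see above), so
  coefficient magnitudes are comparable to the printed ones only up to
  that reconstruction; signs, tests and translations are unaffected.
* Synthetic SCR traces omit habituation and artifacts; responder fractions
  and amplitude distributions are calibrated only coarsely to the reported
  ranges.
* The Laplace marginal likelihood differs from exact integration by up to
  a few hundredths of a log-likelihood unit at very small cluster sizes;
  at the study's 240 trials per subject the approximation error is
  negligible relative to sampling variance.
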