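---
title: "Modelling threat extinction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling threat extinction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extinctrl)
```

## The problem

In differential fear conditioning, a cue (CS+) is paired with an
aversive electrotactile stimulus (US) while a second cue (CS−) never
is. During extinction the US is withheld, and the violation of the
learned expectation — the prediction error at the moment the US fails
to arrive — is thought to drive the transition from threat to safety.
This package implements the quantitative machinery for such a
three-day experiment (acquisition, extinction, retrieval with
reinstatement): the trial schedules, a trial-by-trial learning model
for binary US-expectancy reports, model-derived fMRI regressors,
skin-conductance and fear-rating contrasts, and a mediation analysis
linking a pharmacological manipulation (L-DOPA vs placebo during
extinction) to later threat recovery through prefrontal activity.

## The hybrid learning model

The Rescorla–Wagner/Pearce–Hall hybrid couples an error-driven value
update with a dynamic learning rate. Writing `RO_t ∈ {0, 1}` for the
received outcome, `v_t` for the expected value entering trial t and
`η_t` for the associability:

* `PE_t = RO_t − v_t`
* `v_{t+1} = v_t + α · η_t · PE_t`
* `η_{t+1} = ω · |PE_t| + (1 − ω) · η_t`

Both recursions are convex combinations, so `v` and `η` stay in [0, 1]
whenever `α, ω ∈ [0, 1]`, `η0 ≤ 1` and outcomes are binary — a property
the test suite asserts over random draws. Binary "do you expect the
US?" reports are linked to value through a softmax,
`p_t = 1/(1 + exp(−v_t/β))`, and fitted by Bernoulli maximum
likelihood.

### Timing and parenthesisation conventions

Two details of the update equations are under-determined by their usual
compact notation and are fixed here as follows. First, the
associability entering trial t's value update is the one carried over
from trial t−1, with `η_1 = η0 = 1`; the update to `η` happens after it
has been used. Second, the associability update is read as
`ω·|PE_t| + (1−ω)·η_t` — the absolute prediction error enters, as in
the standard Pearce–Hall formulation, even though compact renderings of
the equation often omit the bars.

### The softmax scale parameter

`β` is conventionally described as an inverse temperature, but it
enters as a divisor of value, so *larger* `β` flattens `p` towards 0.5.
The formula is implemented exactly as conventionally printed, without
recentring `v`. A consequence worth stating plainly: because `v ≥ 0`,
the model can never produce a below-chance probability of a "yes"
report. `p` lives in (0.5, 1), and for `β` in the plausible 0.5–4 range
it is squeezed into roughly (0.5, 0.88). This has major identifiability
consequences (see *Known limitations*).

### Defaults and their meaning

| parameter | default | meaning |
|---|---|---|
| `v0` | 0.75 | initial value = CS+ reinforcement rate in acquisition |
| `eta0` | 1 | first update fully driven by the prediction error |
| `alpha` start | 0.5 | learning-rate initialisation for the optimizer |
| `omega` start | 0.5 | associability-weight initialisation |
| `beta` start | 4 | softmax-scale initialisation |
| likelihood clip | 1e−9 | keeps log-likelihood finite at saturated `p` |

Missing reports are sentinel-coded (`n/a` in files, `NA` in memory) and
masked out of the likelihood sum; the latent recursion still runs over
every trial because learning is outcome-driven, not report-driven.

## Fitting

`fit_subject()` minimises the negative log-likelihood with Nelder–Mead
on an unconstrained scale: logistic transforms for `α` and `ω`, and a
scaled logistic `β = 50·plogis(x)` for `β`. (A pure log transform has
no upper bound and a hard cap is non-smooth; the scaled logistic keeps
the printed start interior and respects the (0, 50] box.) Because the
likelihood surface is multimodal — narrow basins at small `ω` coexist
with broad plateaus — the fitter always evaluates a deterministic 5×5×5
coarse grid first and seeds simplex runs from its three best points, in
addition to the printed start and seeded random restarts drawn from
`α, ω ~ U(0.1, 0.9)`, `β ~ U(0.5, 4)`. Fits with any parameter at its
box edge, or with `β < 0.01` (which saturates the softmax), carry a
`boundary` flag. `fit_subject_multi()` shares one parameter triple
across several streams — e.g. the CS+ stream at `v0 = 0.75` and the
CS− stream at `v0 = 0`, or replicate sessions in recovery studies.

## fMRI regressors

Events are zero-duration sticks (CS+ onsets, CS− onsets, and
US-omission onsets at CS+ onset + 5 s on unreinforced trials) placed on
a 0.1 s microtime grid, convolved with the canonical double-gamma HRF
(peak 6 s, undershoot 16 s, ratio 1/6, peak-normalised), and sampled at
the scan grid (TR = 1.493 s by default). Parametric modulators are
mean-centred and placed on their parent events; the associability
modulator is residualised on the prediction-error modulator *before*
convolution (serial orthogonalisation), since convolution preserves
orthogonality only approximately. High-pass filtering, autocorrelation
modelling and motion regressors are deliberately out of scope: the GLM
here is a desk-scale harness for noiseless and white-noise recovery
checks, not a replacement for a full first-level analysis.

## Psychophysiology

Skin-conductance amplitudes are transformed as `ln(1 + SCR)` — the
`1 +` is required because non-reactions are scored as zero, for which a
bare logarithm is undefined; the transform is configurable for users
who prefer `ln(SCR)` on positive trials. The range-correction maximum
is taken across both CS types within subject and day, so every
subject-day with any response has a corrected maximum of exactly 1.
Fear ratings (VAS 0–100) are divided by the day maximum. Day-3
statistics honour the separation between the retrieval test (first 8 +
8 trials, analysed alone) and the reinstatement test; reinstatement
contrasts compare the last k pre-US trials with the first k post-US
trials (k = 3 for the transient effect, k = 8 for whole blocks).
Subject-days missing more than a configurable third of trials can be
excluded with `exclusion_filter()`.

## Mediation

`fit_paths()` fits `M ~ 1 + T` and `Y ~ 1 + T + M` by OLS with
treatment coded placebo = 0, L-DOPA = 1 and no treatment–mediator
interaction. The quasi-Bayesian ACME draws coefficients from each
model's asymptotic normal independently (the model-wise choice; a joint
draw across models is not identified from separate OLS fits), forms
`a_i·b_i`, and reports the median of draws (robust to the product
distribution's skew; the mean is also kept), a percentile interval, and
a two-sided Monte-Carlo p floored at 1/n_draws. Ties at zero count for
both tails so a degenerate zero-variance product yields p = 1. The
bootstrap variant resamples subjects, redrawing any resample whose
treatment column collapses to one level or whose mediator becomes
collinear.

## The synthetic-data generator: what it does and does not emulate

`generate_cohort()` states the following world: 22 placebo and 24
L-DOPA subjects; learning parameters drawn from *identical*
distributions in both groups (logit-normal `α` centred at 0.35,
logit-normal `ω` centred at 0.4, log-normal `β` centred at 1.5 — mild,
realistic heterogeneity chosen once; a config switch can inject a group
shift for power studies); binary day-2 ratings generated by each
subject's own hybrid parameters; a vmPFC proxy shifted between groups
by a = −2.2957 with residual SD 1.3; differential retrieval SCR built
from the vmPFC proxy with b = −0.01898, no direct effect, residual SD
0.05; trial-wise corrected SCR as `0.1 + 0.6·v_t` plus clipped Gaussian
noise (a modelling convention — the simplest monotone link between
declining value and declining CS discrimination, not an empirical
claim); and BOLD as design × betas plus white noise.

A green test on this world establishes that the *pipeline* recovers
what the generator put in. It does not establish anything about real
SCR waveforms, physiological or scanner noise, non-stationary learning,
or group differences in learning parameters (the generator's default is
the behavioural null).

## Numerical choices

Likelihood clipping at 1e−9; simplex relative tolerance 1e−10 with at
most 2000 iterations; ITIs sampled from the discrete set {7, …, 11} s
with weights (0.55, 0.2, 0.15, 0.05, 0.05), the simplest distribution
honouring both the stated 7–11 s range and 7.8 s mean (the true
distribution is not documented; the weights are configurable);
constrained trial orders by constructive sampling with restart (at most
2 consecutive same-CS trials) and rejection sampling for reinforcement
placement (at most 3 consecutive reinforced CS+). All randomness is
seed-scoped with `withr::with_seed`, so builders never disturb the
caller's RNG state.

## Known limitations

* **Parameter recovery from binary reports is poor, and the acceptance
  criterion that demands it stays red.** Because the observation model
  confines `p` to (0.5, 1), single trials carry little information, and
  `α`, `ω`, `β` trade off (the product `α·η` is the effective learning
  rate). In-session pilot studies measured recovery correlations with
  the optimizer even started at the truth: near zero for all-omission
  streams, r(α) ≈ 0.23–0.26 for cycled acquisition/extinction streams,
  and r(α) ≈ 0.43 for i.i.d. Bernoulli(0.5) outcomes — far below the
  0.7 threshold the recovery criterion asserts (the production fitter
  with its grid pre-scan reaches r(α) ≈ 0.39 and r(ω) ≈ 0 on the cycled
  design; only the β correlation clears its 0.5 bar). This is a
  property of the model as printed, not of the optimizer; a recentred
  observation model (`v − 0.5`) or continuous expectancy ratings would
  be needed to change it, and both are out of scope.
* Fits on a single 24-trial extinction stream frequently sit on
  parameter boundaries; interpret subject-level point estimates with
  the `boundary` flag in hand, and prefer group-mean latent summaries.
* The GLM stage omits temporal filtering and autocorrelation; its
  t-statistics are for synthetic white-noise data only.
* Whether CS− streams were historically included in fitting is
  ambiguous; the default fits the CS+ extinction stream alone
  (`v0 = 0.75`), with `fit_cohort(..., streams = "both")` available.
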