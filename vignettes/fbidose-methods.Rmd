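---
title: "Adaptive duration finding for the cardio-visual full-body illusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive duration finding for the cardio-visual full-body illusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbidose)
```

## The problem

Extended-reality full-body illusions can reduce pain in chronic pain
conditions. In the cardio-visual variant, a participant views a live video of
their own body from behind while the virtual body flashes in synchrony with
their heartbeat; the resulting sense of ownership over the virtual body is
thought to recalibrate distorted multisensory body representations implicated
in fibromyalgia. Session duration is a genuine dose: too short and no
illusion (or analgesia) develops, too long and headset weight, posture and
fatigue make the session intolerable.

`fbidose` packages four things around this problem:

1. the preset cohort escalation/de-escalation **rule engine** used to find a
   duration balancing benefit and tolerability, with full-trial replay;
2. a **synthetic-participant simulator** for closed-loop trials and
   operating-characteristic studies of that design;
3. the **analysis stack** for the trial outcomes (polynomial dose-response
   fits, nested-model likelihood-ratio tests, paired t tests with Cohen's
   *d*, correlation, baseline-adjusted ANCOVA with estimated marginal
   means), plus questionnaire scoring for the instruments used at intake;
4. the real-time **ECG-to-visual synchrony** algorithm (filtering, R-peak
   detection, fixed-timestep rendering) in an offline, auditable emulation.

The per-participant dataset of the original 20-participant, seven-cohort
study ships with the package (`fbi_trial()`), so every reported statistic can
be recomputed offline.

## The adaptive design

Cohorts of three (occasionally two) participants receive the same target
duration. A duration is **tolerable** when at least two members complete it,
and **beneficial** when at least two show an immediate reduction of at least
one point on the 11-point pain-intensity numeric rating scale (NRS). The
first cohort receives 2 min. Then:

* **Rules 1-2.** A tolerable duration (beneficial or not) is doubled for the
  next cohort.
* **Rule 3a.** An intolerable duration is reduced by half of the previous
  dose increment (32 after 16 would fall back to 24).
* **Rule 3b.** If the 3a candidate is at least as long as a duration at
  which some earlier participant had to stop, the maximally tolerated region
  has been bracketed: the next target is instead the midpoint of the two
  highest tolerated durations.
* **Rule 4.** A de-escalated duration that proves tolerable and beneficial
  is increased again; a tolerated midpoint duration is repeated in a fresh
  confirmation cohort.
* **Rule 5.** When a confirmation cohort also finds the duration tolerable
  and beneficial, the trial stops and that duration is recommended.
* **Rule 6.** After at least one beneficial duration, two consecutive
  tolerable target durations with no further reduction in pain intensity
  also stop the trial.

Several points are under-specified in that prose and had to be fixed as
design choices:

* *Rule 6 baseline.* "No further reductions" is operationalised as: the
  cohort's mean immediate NRS reduction does not exceed the best mean
  reduction of any earlier cohort. The predicate is isolated in one place in
  the engine.
* *Rule 6 recommendation.* A rule-6 stop recommends the tolerable beneficial
  duration with the largest mean reduction observed.
* *Rule 3b comparison.* The candidate-versus-abort comparison is inclusive
  (`>=`) by default; a strict reading is available via
  `dose_rules_config(strict_3b = TRUE)`. Both reproduce the packaged trial.
* *First-cohort intolerance.* With no previous increment, the increment is
  defined as the starting dose, so the fallback is half the starting dose,
  preserving the geometric spirit of the ladder.
* *Increase after a plain de-escalation.* The engine doubles, consistent
  with every other escalation.
* *Termination guarantee.* Simulated trials stop after `max_cohorts`
  (default 12) cohorts regardless; such stops are labelled `"cap"` and never
  carry a recommendation.

`replay_trial()` re-derives every verdict and decision from the raw member
records and verifies that the observed ladder is exactly the one the rules
prescribe; a dose ladder that the rules could not have produced is an error,
while an intolerable dose below a tolerated one (which the rules do not
forbid) is recorded as a consistency warning. `next_decision()` is a pure
function of the cohort history, so replays are deterministic.

```{r replay}
trace <- replay_trial(fbi_trial())
trace
```

## The analysis stack

**Change scores** are later minus earlier (negative NRS change = pain
relief; positive threshold change = hypoalgesia).

**Duration predictor.** Dose-response models use the duration each
participant actually experienced. By default early terminators contribute
whole minutes (`regression_durations()` floors their achieved durations;
completers are unaffected). This is the convention of the original analysis
— its model table is reproduced exactly at printed rounding only with
whole-minute aborted durations (22 and 18 min), while the packaged table
stores the stopwatch values (22.2 and 18.05 min) and an exact mode is
available with `whole_minutes = FALSE`.

**Polynomial fits.** `fit_polynomial()` is ordinary least squares on the raw
basis $\{1, d, d^2\}$ with classical Gaussian summaries; the log-likelihood
is the Gaussian maximum-likelihood value $-\tfrac{n}{2}(\ln(2\pi\,
\mathrm{RSS}/n) + 1)$, so the nested-model statistic in `lrt()` reduces to
$n \ln(\mathrm{RSS}_\text{reduced}/\mathrm{RSS}_\text{full})$ on 1 degree of
freedom for linear versus quadratic. No small-sample correction is applied:
inference is plain t/F throughout, two-sided, with multiplicity adjustment
only in the ANCOVA pairwise table.

**Paired tests.** `paired_t()` uses the standard deviation of paired
differences (n − 1 denominator); Cohen's *d* is the mean difference over
that standard deviation, and its 95% interval comes from noncentral-t
inversion of the observed statistic. Intervals are always reported (low,
high). Zero-variance differences are an error rather than a silent zero.

**ANCOVA.** `ancova()` fits `post ~ pre + group`. Effect F statistics use
drop-term (Type III) sums of squares against the full-model residual mean
square — for the group factor, entered last, this equals the incremental F
over the covariate-only model. Eta-squared is each effect's drop-term sum
over the total of both effect sums plus the residual sum, the convention of
common point-and-click ANCOVA software, and the one that reproduces the
original report's covariate statistics; a sequential decomposition does not.
Estimated marginal means are group predictions at the grand-mean covariate;
all `k(k-1)/2` pairwise contrasts carry Bonferroni-adjusted p values. With
the packaged trial the factor has 6 levels (the two 12-min cohorts pool), so
the multiplier is 15. A single-group call degenerates gracefully to the
simple baseline regression.

**Ownership analyses.** The body-ownership item is analysed as a mechanism:
dose-response fits and a Pearson correlation with the immediate NRS change.
The packaged per-participant table yields $r = 0.42$ ($p = 0.068$) for that
correlation and an ownership dose-response likelihood ratio near zero; the
original report's ownership statistics evidently derive from inputs not
recoverable from the published per-participant table, so the toolkit reports
the values the packaged data actually produce (tests pin them to an
independent sum-formula oracle rather than to any published number). The
packaged threshold tests agree with the published ones to the last printed
digit only up to the 2-decimal rounding of the stored threshold values
(t statistics match within 0.01).

## The synthetic population

The simulator draws, per participant at target duration $d$:

* latent tolerance $T \sim \mathrm{LogNormal}(\mu_T, \sigma_T)$; the
  session completes iff $T \ge d$, else it aborts at $T$ minutes;
* baseline pain $\mathrm{NRS}_1$ from an empirical distribution over 0-10
  (default: the packaged trial's baseline frequencies);
* immediate change $\Delta = a\,d_\text{ach}^2 + b\,d_\text{ach} + c +
  \varepsilon$, $\varepsilon \sim N(0, \sigma)$, evaluated at the *achieved*
  duration, mirroring the regression convention; the post score is the
  change added to baseline, rounded half-away-from-zero and clamped to
  0-10 (both behaviours switchable; a `latent` flag exposes the unrounded
  change for exact-recovery tests);
* a Gaussian 24-h drift for the follow-up score, lognormal baseline
  pressure-pain thresholds with an additive positive post shift, and an
  ownership item coupled linearly to the realised pain reduction.

Defaults are study conventions, not biological claims: the quadratic is the
study-calibrated curve $(a, b, c) = (0.02, -0.58, 2.14)$; the tolerance
scale ($\mu_T = 3.12$, $\sigma_T = 0.27$ log-minutes) puts roughly 90% of
participants above 16 min and 10% above 32 min, matching the observed
tolerability pattern; the response noise is one NRS point. The ownership
coupling (slope 0.8, noise 1.5) only fixes the direction of the association.
The generator does not attempt demographics, questionnaire items, or free-
text 24-h symptoms, so simulation-based tests speak to the design's
operating characteristics under this stylised population — integer scores,
a smooth quadratic mean, independent participants — and not to features of
real fibromyalgia data such as serial dependence, floor effects in severe
patients, or informative dropout.

`operating_characteristics()` summarises recommended-dose distributions,
cohort counts and termination modes over replications with Monte-Carlo
standard errors. Under the defaults the modal recommendation is 12 min.

## The synchrony pipeline

The original system polls a three-lead ECG at 500 Hz, low-pass filters it
(fourth-order, zero-phase Butterworth), primes for 10 s to calibrate a
per-participant R-peak threshold, then flags an R peak when the
above-threshold signal's first difference falls to zero or turns negative.
A 50 Hz fixed-timestep renderer consumes flags: a flash resets the body
image to full opacity and releases a particle pulse (fading over 0.5 s);
otherwise opacity drops 2% per step.

Choices the toolkit had to make:

* **Cutoff 25 Hz** (unstated in the original description): retains QRS
  energy, removes mains ripple; configurable.
* **Zero phase is non-causal.** Offline the filter runs forward-backward
  (`signal::filtfilt`), doubling the effective magnitude order. The
  real-time constraint is emulated by a processing-block delay: a detection
  becomes visible to the renderer only at the end of its block (default one
  timestep, 20 ms).
* **Threshold** = 0.6 × the 99.5th percentile of the priming-window
  amplitude. The high quantile is a robust stand-in for the R-apex height
  (the trace spends well under 0.5% of its time near the apex at any
  plausible heart rate), so the threshold sits near 60% of the R height,
  strictly between T and R waves; lower quantiles ride the T-wave shoulder
  and misfire.
* **Refractory 250 ms**: one flag per beat, implied by the flag-consumption
  design; configurable.
* **"Reduced by 2%"** is read subtractively (2 percentage points of full
  scale per step, floor 0, hence a 1.0 s fade); a multiplicative mode is
  available since the wording admits both.
* **Flag handoff**: a flag raised exactly on a timestep boundary is consumed
  at the *next* boundary.

The latency budget follows: up to one block for the flag to surface plus one
timestep for the renderer, so flashes land 20-40 ms after the true apex on
clean signal — the band the original system reports. The audit
(`latency_report()`) matches each ground-truth apex to the first opacity
reset within a window and counts misses and spurious resets.

```{r sync}
pipe <- sync_pipeline(synth_ecg(30, hr_bpm = 60, seed = 1))
pipe$report
```

## Numerical conventions and degenerate inputs

Dose arithmetic is exact decimal minutes with a `1e-9` comparison tolerance
(no rounding of midpoints); NRS rounding is half-away-from-zero;
latencies are snapped to whole microseconds to keep grid arithmetic exact;
confidence intervals are (low, high) everywhere. Empty datasets,
wrong-arity questionnaire responses, out-of-range items, achieved durations
above target, inconsistent completion flags, rank-deficient designs,
zero-variance paired differences, constant correlation inputs and
traces shorter than the priming window all raise informative errors naming
the offending row or field rather than propagating NA.

## Problem sizes used in the checks

The packaged suite runs the full replay and analysis stack on the
20-participant trial; parameter recovery uses 100 replications of 500
participants per dose at six durations; the ANCOVA null calibration uses
500 simulated null datasets of the trial's size and design; detector and
latency properties use 30-120 s of synthetic ECG at 50-100 bpm. These sizes
give stable Monte-Carlo checks (binomial standard errors of about 3
percentage points on coverage) while keeping the default suite fast.

## Known limitations

* The rule engine implements exactly this preset design; it is not a
  continual-reassessment or Bayesian dose-finding framework.
* `replay_trial()` requires the observed ladder to be rule-consistent; it
  cannot audit trials run under a different (or violated) protocol.
* The simulator's population is stylised (see above); operating
  characteristics under realistic fibromyalgia heterogeneity are out of
  scope.
* The synchrony module is an offline emulation for algorithm auditing, not
  a hardware acquisition or rendering layer; true real-time behaviour of a
  zero-phase filter is necessarily approximated (the block-delay emulation
  makes that approximation explicit and configurable).
* Analyses assume complete data; there is no imputation machinery, and no
  minimally-important-difference estimation.
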