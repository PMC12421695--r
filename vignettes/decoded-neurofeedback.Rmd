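---
title: "Decoded neurofeedback: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoded neurofeedback: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decnef)
```

## The closed loop

`decnef` implements the analysis side of a decoded neurofeedback (NF)
experiment on interoceptive attention. A session consists of an attention
decoder-training task (24 alternating 10-s heartbeat-attention and
visual-attention trials, separated by 12-s rests) followed by three
regulation runs (20-s baseline, then 24 alternating blocks of 10-s rest,
10-s regulation, 6-s rating, 4-s feedback). The loop per regulation block
is:

1. **Features.** ROI voxel time series are expressed as percent signal
   change (PSC) against the run's baseline window, and the last five
   volumes of the regulation period — shifted forward by 2 volumes (~4 s)
   for the haemodynamic delay — are flattened (volume-major) into one
   un-normalised spatiotemporal feature of length `5 × n_voxels`.
   Amplitude is deliberately preserved: no per-feature scaling or
   centering is applied anywhere, and the flattening order is fixed so the
   training and feedback paths see bit-identical layouts.
2. **Decoder.** A linear soft-margin SVM (LIBSVM via `e1071`, `C = 1`,
   features as-is) separates the two attention states; label `+1` is
   interoceptive and positive decision values favour it.
3. **Calibration.** Platt scaling maps the decision value to
   `P(y = 1 | x) = 1 / (1 + exp(A_r f(x) + B_r))`. The fit maximises the
   Bernoulli likelihood with Platt's regularised targets
   `(N₊+1)/(N₊+2)` and `1/(N₋+2)`, which keep `(A, B)` finite even on
   perfectly separated training sets; the orientation constraint `A ≤ 0`
   makes "larger decision value ⇒ larger interoceptive probability"
   well-defined. SVM and calibration are fitted on the same pooled data.
4. **Score.** The displayed NF score is `100 P` on interoceptive blocks and
   `100 (1 − P)` on exteroceptive blocks; 50 is ambiguous, and a trial is
   correct only when its score strictly exceeds 50 (a boundary trial is
   incorrect).
5. **Retraining.** The run-1 decoder is trained on the decoder task only;
   before runs 2 and 3 it is retrained on the decoder task plus all earlier
   regulation runs, in chronological order, so the probability
   transformation stays calibrated as the subject's patterns evolve.

Learning is summarised per subject as
`LE = Run 3 − (Run 1 + Run 2)/2`, applied to both the mean displayed score
and the classification accuracy (CA). The early-run average is used as the
baseline because performance typically jumps between runs 1 and 2 when the
first retraining happens.

## Sham feedback model

Control subjects see scores that are statistically matched to real feedback
but unrelated to their own brain activity. The generative model estimated
from treatment-arm scores consists of: fixed-width score bins (width 10 on
[0, 100] — the bin width is a modelling choice, as score "categories" admit
several definitions), the unconditional bin distribution with per-bin pools
of observed scores, a first-order bin-to-bin transition table from
consecutive within-run trial pairs, and per-run success rates, which
default to the published values (48.512, 58.589, 62.500 %). Sampling a
trial first draws success (`score > 50`) or failure from the run's rate,
then draws a bin from the previous trial's transition row — or the
unconditional distribution for the first trial or an unobserved row —
*truncated and renormalised* to the success/failure range, and finally an
actual score from the bin's empirical pool restricted the same way.
Truncation-plus-renormalisation is how we reconcile the two sampling rules
(rate-driven success and transition-driven temporal structure), which are
individually specified but not their interaction; a variant that conditions
transitions on the previous success/failure outcome instead of the score
bin is available (`condition_on = "outcome"`). Because the success rates
increase over runs, sham subjects see an *apparent* learning effect, while
their "true" scores — computed from their brain data by the identical
decoder pipeline but never displayed — stay flat; the package computes both
and their pooled correlation across all sham trials as a validation
diagnostic.

## Offline MVPA

Trial-wise pattern separability is re-estimated offline with a
least-squares-all beta-series GLM: one regressor per trial (10-s boxcar at
the regulation period convolved with the canonical double-gamma HRF: peak
6 s, undershoot 16 s, unit dispersions, peak:undershoot 6, 32-s support,
peak-normalised), plus intercept and linear drift; rest, rating and
feedback are left unmodelled as the implicit baseline. Ordinary least
squares per voxel yields a 24 × voxels beta matrix per run, classified by
the same linear SVM under deterministic two-fold cross-validation (folds
alternate trial order within condition, so they are class-balanced and
contain no immediate temporal neighbours in the same direction).
Least-squares-all was chosen over least-squares-separate because the
trials are well separated (30-s cycle) so regressor collinearity is mild;
the design-matrix builder reports rank deficiency rather than silently
regularising. The online and offline accuracies are different estimators of
related but distinct quantities (moment-to-moment decodability vs denoised
trial patterns) and are not expected to agree numerically.

## Behavioural measures

Interoceptive accuracy from the heartbeat counting task is
`mean(1 − |recorded − reported| / recorded)` over six trials of 15–65 s.
The formula is not clamped below zero: gross over-reporting legitimately
produces negative scores, and clamping would bias group means. Group-level
inference (one-sample t on learning effects, Pearson correlations of
learning effect with accuracy change, Fisher r-to-z between-group
comparison with `SE = sqrt(1/(n₁−3) + 1/(n₂−3))`) is implemented directly
and cross-checked against `t.test`/`cor.test` in the test suite.
Repeated-measures ANOVAs are deliberately out of scope; the cohort report
exposes per-cell descriptives for external tools.

## The synthetic-data generator

`simulate_cohort()` draws subjects and `simulate_run()` generates ROI time
series with the structure the analysis assumes:

* **Signal.** Each subject has two condition-specific voxel patterns.
  A fraction `pattern_sparsity` (default 0.05) of ROI voxels is
  informative, with amplitudes drawn `N(0, 1)` in percent signal change —
  about 1 % responses in a small discriminative subset, which is how
  fine-grained attentional states present in a real ROI. Patterns enter as
  10-s boxcars over their condition's regulation periods, convolved with
  the canonical HRF.
* **Noise.** Voxel-wise AR(1) (lag-1 correlation 0.3) with marginal sd
  `noise_sd` (default 45, percent units), plus one shared sinusoidal drift
  per run (period 128 s, random phase, default amplitude 1 %). `noise_sd`
  is an *effective* noise parameter: real scanner noise is smaller per
  voxel but spatially and temporally structured in ways an i.i.d. model
  cannot represent, so matching realistic single-trial decoding difficulty
  with independent noise requires inflating its variance. The default was
  calibrated so that run-level online CA starts near chance and ends in
  the low-to-mid 0.6s for a learning cohort — the operating range of
  single-session interoceptive decoding — rather than to any per-voxel
  noise measurement.
* **Learning.** Each NF subject draws a learnability `λ`: with
  probability 0.4 they are a non-learner (`λ = 0`, reflecting the commonly
  reported ~40 % neurofeedback-inefficiency prevalence); otherwise
  `λ ~ N(5, 1.5²)` truncated at 0. Under contingent feedback the pattern
  amplitude of run `r` is scaled by `1 + λ r`; learning is modelled as
  separability growth, not noise reduction, matching the observation that
  discriminability can improve without mean-activation change. Sham
  subjects draw `λ` like everyone else but it is never realised — that is
  the operational meaning of feedback contingency here. A variant where
  growth accrues with the feedback actually received is available
  (`learning_mode = "feedback_driven"`).
* **Behaviour.** Recorded heartbeats follow the subject's (session-
  specific) heart rate with count jitter; reported beats are the recorded
  count times a perception fraction, raised for NF subjects by
  `behaviour_coupling × LE(CA)` using the *displayed* learning effect —
  what the subject actually experienced — plus integer reporting noise.
  `behaviour_coupling` (default 0.15) was calibrated so the NF-arm
  correlation between LE(CA) and the accuracy change sits near 0.55, the
  centre of the plausible range for this kind of brain–behaviour coupling;
  sham subjects have zero coupling because their displayed scores carry no
  information.

Seeds are split per subject and per run through a counter-based scheme, so
every cohort, session and run is reproducible from one master seed.

**What passing tests do and do not show.** The generator reproduces the
*design* of the experiment (timing, feature structure, contingency,
matched sham statistics) and first-order signal statistics. It does not
simulate motion, physiological noise cycles, spatially correlated noise,
scanner drift nonstationarity, or strategic behaviour changes; conclusions
about the pipeline's robustness to those must come from real data.

## Numerical choices

* SVM optimiser tolerance defaults to 1e-8; oracle comparisons in the test
  suite use an exact hand-rolled SMO dual solver and measure *relative*
  primal-objective agreement (LIBSVM's termination rule leaves an absolute
  objective floor around 1e-6 at objective scale ~10 regardless of
  tolerance).
* The Platt fit is a damped Newton iteration with backtracking line search
  and a 1e-12 Hessian ridge; in the degenerate case where the
  likelihood prefers `A > 0` (anti-oriented decisions), `A` is clamped to 0
  and the intercept refitted in closed form.
* Feature windows, baselines and block timings are half-open second
  intervals mapped to 0-based post-dummy volume indices; the decoder task
  appends a 4-s washout fixation so shifted feature windows stay inside
  the run.
* The published acquisition volume counts (202 / 298) are inconsistent
  with the block arithmetic of the published timings (264 / 370 at
  TR = 2 s); run length is therefore derived from the schedule, with an
  override to emulate truncated acquisitions.
* A tie at score exactly 50 counts as incorrect (strict inequality).
* Degenerate inputs error loudly: zero baseline means name the offending
  voxel, rank-deficient GLM designs are rejected, single-class training
  sets are rejected.

## Problem sizes used in validation

The test suite validates statistical behaviour at the study's own scale:
100 replicate cohorts of 28 NF + 26 sham subjects (150 voxels, full
session structure, offline MVPA disabled in the replicate loop for speed)
for the learning-structure recovery checks; 50 replicate 26-subject sham
arms (1,872 trials each) for feedback independence; 100,000 sampled trials
for sham success-rate calibration; 200 null subjects for the chance-level
control. These sizes give binomial standard errors of 2–3 % on the
reported pass fractions.

## Known limitations

* The real-time path assumes motion-free, pre-aligned input; real-time
  realignment and physiological regressors are out of scope.
* The sham model pools the whole treatment arm (no per-subject yoking);
  yoked designs would need per-subject score sets.
* Platt calibration is the only probability mapping offered.
* The i.i.d.-noise generator overstates how much information survives
  spatial averaging; its noise variance is an effective parameter, not a
  physical one.
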