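# decnef

Simulation and analysis of **decoded real-time fMRI neurofeedback** (NF)
experiments targeting interoceptive attention.

In a decoded NF paradigm, a participant alternates between attending to their
heartbeat (interoceptive blocks) and to a subtle visual stimulus
(exteroceptive blocks) while a linear classifier, trained on their own
insula activity, decodes the attentional state in real time and feeds a
score back after every regulation block. `decnef` re-implements this entire
closed loop as reusable, tested R functions, together with a synthetic-data
generator that emulates the statistical structure of such an experiment, so
the complete analysis can be exercised and validated end to end without
scanner data.

## What the package computes

**Online decoding.** ROI voxel time series are converted to percent signal
change (PSC) against the initial baseline window,
`psc = 100 (x - m) / m`. Each regulation block contributes a spatiotemporal
feature: the un-normalised PSC values of the last five volumes of the block
across all ROI voxels. A linear soft-margin SVM (LIBSVM, `C = 1`) is trained
on the labelled features; its decision value `f(x)` is mapped to a
probability by Platt scaling,

    P(y = 1 | x) = 1 / (1 + exp(A_r f(x) + B_r)),

with `(A_r, B_r)` re-fitted before every regulation run `r` on all data seen
so far (incremental retraining: run 1 uses the decoder-training task; runs 2
and 3 add the earlier regulation runs). The displayed score is
`100 P` on interoceptive blocks and `100 (1 - P)` on exteroceptive blocks,
so higher always means "more like the instructed state"; a trial counts as
correct when the score strictly exceeds 50. Run-level performance is the
mean score and the classification accuracy (CA, fraction of the 24 trials
correct), and learning is summarised as

    Learning Effect = Run 3 - (Run 1 + Run 2) / 2.

**Sham (yoked) feedback.** For control participants the displayed scores
come from a generative model of the treatment group's scores: fixed-width
score bins, an empirical unconditional distribution, a first-order
transition table between bins, and per-run success rates
(48.512 / 58.589 / 62.500 % for runs 1–3); each trial first draws
success/failure from the run's rate, then a score from the (transition or
unconditional) distribution restricted to the matching range. Sham scores
are therefore statistically matched to real feedback but independent of the
recipient's brain activity — which the package verifies.

**Offline MVPA.** A least-squares-all GLM estimates one beta per trial (10-s
boxcars convolved with the canonical double-gamma HRF, plus intercept and
drift), and a two-fold cross-validated linear SVM measures pattern
separability per run.

**Behaviour.** The heartbeat counting task is scored as
`mean(1 - |recorded - reported| / recorded)` over six trial durations
(15–65 s), and group statistics (one-sample t on learning effects, Pearson
correlations between learning effects and accuracy change, Fisher r-to-z
group comparison) are computed with directly implemented formulas.

## Worked example

```r
library(decnef)

cfg <- cohort_config(n_nf = 2, n_sham = 1,
                     params = acquisition_params(n_voxels = 40))
report <- run_cohort_experiment(cfg, seed = 11)

report$sessions[[1]]$true_summaries[, 1:3]
#>   run_index mean_score classification_accuracy
#> 1         1     55.695                 0.66667
#> 2         2     58.609                 0.66667
#> 3         3     80.350                 0.79167

report$outcomes[, c("group", "le_score", "le_ca", "delta_ia")]
#>   group le_score  le_ca delta_ia
#> 1    NF   23.198 0.1250  0.00632
#> 2    NF    2.570 0.0625  0.01430
#> 3  Sham    6.083 0.0625 -0.03434
```

The first subject (a strong learner in this draw) improves over the three
regulation runs as their patterns separate and the decoder is retrained;
the outcome table gives each subject's learning effects (`le_score` in
score points, `le_ca` as a CA fraction) and the pre-to-post change in
heartbeat-counting accuracy. This toy configuration (40 voxels, 3
subjects) is noisy by construction; at the default study scale (28 NF +
26 sham, 150 voxels) the cohort report additionally contains group
statistics and the sham-validation correlation over all 1,872 sham-arm
trials.

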