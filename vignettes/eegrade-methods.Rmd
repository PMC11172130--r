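---
title: "Methods: PLI connectivity and four-level anxiety grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity and four-level anxiety grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Generalized anxiety disorder (GAD) is clinically graded into four levels —
normal, mild, moderate, severe — by the total score of the Hamilton Anxiety
Rating Scale (HAMA): below 7, 7–17, 18–24, and above 24 respectively (both
interior boundaries inclusive; `hama_to_grade()`). Because the scale relies
on self-report, there is interest in objective electrophysiological
correlates. This package implements a complete analysis pipeline that grades
subjects from 10 minutes of resting-state EEG recorded on 16 scalp
electrodes of the international 10–20 system (FP1, FP2, F3, F4, C3, C4, P3,
P4, O1, O2, F7, F8, T3, T4, T5, T6), using phase-lag functional connectivity
and gradient-boosted trees.

Clinical recordings of this kind are not redistributable, so the package
ships a synthetic cohort generator that reproduces the statistical structure
the analysis relies on. Every stage is exercised end to end on simulated
data; nothing in the pipeline is specific to simulation.

## The connectivity feature: Phase Lag Index

For a band-limited signal $x(t)$, the analytic signal
$z(t) = x(t) + i\,H[x](t)$ (with $H$ the Hilbert transform, implemented in
the frequency domain) defines the instantaneous phase
$\varphi(t) = \arg z(t)$. For two channels with phases $\varphi_1, \varphi_2$
the Phase Lag Index is

$$\mathrm{PLI} = \left|\left\langle \operatorname{sign}\big(\Delta\varphi(t)\big)\right\rangle_t\right|,
\qquad \Delta\varphi = \varphi_1 - \varphi_2 \ \text{wrapped to } (-\pi, \pi].$$

PLI is 0 when phase differences are symmetric around zero and 1 when one
channel consistently leads the other. Its virtue for scalp EEG is that
zero-lag relationships — exactly what instantaneous volume conduction
produces — contribute $\operatorname{sign}(0) = 0$ or symmetric sign
fluctuations, so spurious mixing-driven "connectivity" is suppressed.
Numerical conventions that matter and are fixed here: the phase difference
is wrapped *before* taking the sign; $\operatorname{sign}(0) = 0$; no
samples are trimmed after the Hilbert transform (epochs are at least 2 s at
125 Hz, so boundary leakage is negligible relative to estimator noise — a
trim could be added upstream via the `pre_clean` hook if needed).

Features are computed per epoch for the four canonical rhythms — theta
(4–8 Hz), alpha1 (8–10 Hz), alpha2 (10–13 Hz), beta (13–30 Hz) — over all
$16 \cdot 15 / 2 = 120$ electrode pairs, giving a fixed 480-dimensional
vector. The index map (`feature_index()`) orders bands canonically and pairs
lexicographically in montage order; feature names follow `band_chA_chB`.

## Preprocessing

`preprocess_recording()` applies, in order:

1. **Broadband filter**: 4th-order Butterworth band-pass, 4–30 Hz, applied
   forward–backward (`signal::filtfilt`) so the net filter is zero-phase,
   with 3 s of odd-reflection padding at each end so start-up transients
   decay inside the discarded pad rather than in the data.
   Since the downstream feature *is* a phase statistic, causal filtering
   with its frequency-dependent group delay would corrupt it; zero-phase
   filtering is the single most consequential implementation choice in the
   pipeline and is asserted by test (cross-correlation peak at lag 0).
2. **Decimation** by 2, from 250 Hz to 125 Hz. Safe because the signal is
   already band-limited to 30 Hz.
3. **Epoching** into non-overlapping windows of 2–14 s; a trailing
   remainder is discarded, so a recording of duration $D$ yields
   $\lfloor D/w \rfloor$ epochs.
4. **Band decomposition** of each epoch with zero-phase 4th-order
   Butterworth filters at the four canonical bands.

Epochs are filtered broadband *before* segmentation and band-decomposed
*after*, keeping epochs independent of each other. Artifact removal (on
real recordings: ocular, cardiac, myogenic) is delegated to the `pre_clean`
hook of `broadband_filter()`, which defaults to the identity — synthetic
cohorts are generated artifact-free, and any ICA-based cleaner operates on
information (artifact topographies) that only real data contain.

## The synthetic cohort

`simulate_cohort()` emulates exactly the structure the analysis assumes:

* Each channel is a sum over bands of unit-RMS narrowband oscillations
  (white noise through the band's Butterworth filter — *not* pure tones,
  whose degenerate phase would make PLI trivially 0 or 1 and hide bugs)
  plus broadband Gaussian noise (`noise_sd`, default 0.5 relative to unit
  band amplitude).
* Class structure is planted as phase-lag coupling on selected edges: for
  an edge $(i, j)$ with strength $\kappa$ and lag $\delta$, channel $j$'s
  band component is $\kappa \cdot s_i(t - \tau) + \sqrt{1-\kappa^2} \cdot
  s_j(t)$, where $\tau$ realizes $\delta$ radians at the band's center
  frequency as an exact fractional-sample (frequency-domain) delay. The
  default structure places beta-band coupling on four frontal–temporal
  pairs (F3–T3, F4–T4, F7–T5, F8–T6) with $\kappa = 0, 0.3, 0.6, 0.9$ for
  normal/mild/moderate/severe and $\delta = \pi/4$ — severity expressed as
  progressively stronger beta frontal–temporal phase coupling.
* Volume conduction is a zero-lag mixing $(1-m)I + mK$ across channels,
  with $K$ a Gaussian-falloff kernel on a schematic 2-D electrode layout
  (constants versioned in `montage_1020()`), $m = 0.1$ by default. Because
  the mixing is instantaneous it must *not* create PLI — this is asserted
  as a property test, and it is the reason PLI was chosen over coherence.
* Optionally the planted lag drifts slowly around $\delta$
  (`phase_jitter_sd`, radians at band center). The window-length
  experiments use 0.6 rad (~34°), a moderate drift that keeps short-window
  PLI estimates visibly noisier than long-window ones without destroying
  the coupling.
* HAMA scores are drawn uniformly from the grade's interval (severe capped
  at the scale maximum 56), so labels and scores are mutually consistent.

What the generator does **not** emulate: artifacts, non-stationarity beyond
the lag drift, realistic head-model mixing, 1/f spectra, or any claim about
real GAD physiology — the coupling strengths are free parameters chosen so
that the pipeline has a detectable but non-trivial signal to recover.
Passing tests therefore demonstrate that the machinery recovers planted
structure of the assumed kind, not that the clinical effect itself is
reproduced.

## Class imbalance: combined cleaning and resampling (CCR)

`ccr_resample()` implements the two-step procedure: around every minority
point a sphere is grown by spending an energy budget — expanding the radius
costs $(k+1)$ per unit when $k$ majority points are inside — majority
points strictly inside a final sphere are pushed radially to its surface
(cleaning the class boundary), and synthetic minority points are drawn
uniformly inside the spheres, with per-point quotas proportional to the
inverse radius so that "unsafe" minority points near the majority receive
more synthetics. Defaults that had to be chosen here: energy is
$0.25 \times$ the median pairwise distance of the training set (scale-aware;
PLI features are already commensurate in $[0,1]$, so distances are plain
Euclidean with no internal standardization); the target policy balances
every non-largest class to the largest, processed rarest first; in the
multiclass rounds only points of classes with strictly more original
samples are displaced, so the original rows of every resampled class
survive unchanged. CCR is applied inside training folds only — the
cross-validation driver never lets evaluation rows reach it.

## Models and hyperparameter search

`boost_spec()` puts three gradient-boosting backends behind one interface
(fit, predict, gain-based feature importance). xgboost is a hard dependency
and the default; LightGBM and CatBoost are honored if their R packages are
installed. The tuned search spaces are fixed per backend: LightGBM
(`num_leaves` 16–96, `min_data_in_leaf` 2–60, `feature_fraction` 0.75–1,
`learning_rate` log-uniform 5e-3–0.1), xgboost (`learning_rate` log-uniform
5e-3–0.1, `depth` 3–10, `min_child_weight` 1–5, `colsample_bytree` 0.5–1),
CatBoost (`max_depth` 5–8, `l2_leaf_reg` 1–5, `learning_rate` log-uniform
5e-3–0.1). Integer bounds are inclusive; log-uniform bounds are given on
the log scale. Untuned parameters keep library defaults, except the number
of boosting rounds, which xgboost's R interface does not default; the
package uses 50, which saturates training loss at the feature-table sizes
this pipeline produces.

`tpe_search()` is a tree-structured Parzen estimator with the standard
univariate factorization: a random startup phase (10 trials), a split of
observed trials into the top 25% ("good") and the rest, kernel-density
models of both groups per parameter (bandwidth $1.06\,\hat\sigma n^{-1/5}$
floored at 1/20 of the range), and greedy selection among 24 candidate
vectors by the good/rest density ratio. The budget is 30 evaluations by
default. Tuning is evaluated on an inner stratified split of the training
fold, never on the outer test fold — evaluating the objective on the test
fold, a protocol sometimes described loosely in applied work, leaks labels
into model selection; the package does not offer that shortcut.

## Evaluation

`compute_metrics()` derives from a $C \times C$ confusion matrix: accuracy
(trace over total), per-class recall (diagonal over row sum — reported as
the per-group accuracy of a grading system), macro F1 (mean of
$2\,TP_c/(2\,TP_c + FP_c + FN_c)$; a class with no true and no predicted
members contributes 0), macro G-mean (geometric mean of recalls, zero as
soon as one class is never recovered), and Cohen's kappa with the
multiclass chance agreement $P_e = \sum_c r_c c_c / n^2$ — the binary
product formula is its special case, and a four-class task requires the
general form. Degenerate single-class matrices ($P_e = 1$) get kappa 0.

The protocol is stratified 5-fold cross-validation repeated 3 times
(`repeated_stratified_cv()`), reporting mean ± sd over the 15 test folds.
Splits are epoch-level by default, which matches how sample counts are
usually tabulated in this literature but lets one subject contribute to
both train and test folds; for subject-level generalization claims,
aggregate with `extract_features(average_epochs = TRUE)` (one row per
subject) instead. `time_window_sweep()` repeats the whole pipeline per
window length (2–14 s).

## Feature selection

`rfe_early_stop()` removes one feature per iteration — the lowest
fold-averaged gain importance over 5 stratified folds, the same fits that
produce the iteration's pooled CV metrics. Two places needed decisions the
literature leaves open:

* **Stopping.** Iteration stops when `patience` (default 10) consecutive
  iterations each fail to strictly improve on the iteration before them.
  A constant trace therefore stops after exactly `patience + 1`
  iterations. The alternative — comparing against the best value so far —
  couples the stopping horizon to the discrete granularity of a
  cross-validated accuracy (at $n$ test epochs the metric can only take
  $n+1$ values, so at small $n$ elimination halts after a handful of
  iterations regardless of how much redundancy remains); comparing to the
  previous iteration keeps the horizon tied to the information in the
  trace.
* **Ties.** Gain importances of never-split features are exactly zero, so
  large tie groups are the norm, not the exception. Features are indexed
  band-contiguously, so any index-based tie rule systematically strips one
  band first and the surviving subset's band composition then reflects
  indexing order rather than information — it would corrupt precisely the
  attribution the selection feeds. Ties at the minimum are therefore
  broken by a seeded random draw (deterministic given the master seed).

The optimal subset is the one with the highest cross-validated accuracy
anywhere in the trace, ties resolved toward the smaller subset. The final
quality of that subset is then re-estimated with the evaluation module's
repeated CV (`run_pipeline()` does this as `cv_best`), not taken from the
selection loop's own folds.

## Attribution

`decode_features()` inverts the feature index into (band, electrode pair,
lobes). `rhythm_distribution()` counts selected features per band;
`region_distribution()` counts edge *endpoints* per lobe — each edge
credits both its lobes, an intra-lobe edge credits its lobe twice, so
counts sum to twice the subset size (the handshake identity). Endpoint
counting was chosen because per-region connection counts are otherwise
ambiguous for inter-lobe edges; `region_rhythm_table()` reports the full
region × band cross-table so either marginal reading is recoverable. Note
the montage itself is not region-balanced (6 frontal, 4 temporal, 2 each
central/parietal/occipital electrodes), so endpoint fractions should be
compared against that baseline, not against uniformity.

## Problem sizes used by the test suite

The shipped experiments run at deliberately small scale: cohorts of 3
subjects per grade × 60 s for the end-to-end recovery and window-trend
experiments (72 epochs at 10 s windows), 2 subjects per grade × 20 s for
unit fixtures, and $n = 500$, 50-feature designs for selection-recovery
checks. These sizes are large enough for the planted effects to be
detectable by design and small enough that the whole suite runs on one CPU
in minutes. The stochastic end-to-end checks are evaluated over three
seeds with majority logic, reflecting that single runs at this scale have
real variance.

## Known limitations

* Only PLI is implemented; weighted PLI, imaginary coherence and other
  estimators less conservative about near-zero-lag coupling are out of
  scope.
* Epoch-level CV splits are optimistic for subject-level claims (see
  above).
* The EDF writer/reader covers plain EDF with equal per-signal rates —
  sufficient for this pipeline's cohorts, not a general EDF library.
* Gain-based importance is the only ranking driving RFE; at very small
  sample sizes it is noisy, and the selected subset should be read
  together with its attribution tables rather than as a definitive edge
  list.
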