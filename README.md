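# eegrade

`eegrade` is an R package for grading generalized anxiety disorder (GAD)
into four severity levels — normal, mild, moderate, severe — from
resting-state EEG. It is aimed at researchers in clinical neurophysiology
and machine learning who want a complete, reproducible
connectivity-to-classification pipeline, and it ships a synthetic cohort
generator so every stage is testable without access to clinical
recordings.

## What it computes

The severity signal is carried by **Phase Lag Index (PLI)** functional
connectivity. For two channels with instantaneous phases
φ₁(t), φ₂(t) (from the Hilbert analytic signal),

    PLI = | ⟨ sign(Δφ(t)) ⟩ₜ | ,   Δφ = φ₁ − φ₂ wrapped to (−π, π]

PLI is 0 for symmetric (in particular zero-lag, volume-conducted) phase
relationships and 1 for a consistent lead/lag — a conservative coupling
measure for scalp EEG. Connectivity is computed per epoch over all 120
pairs of a 16-electrode 10–20 montage in four rhythms (θ 4–8, α1 8–10,
α2 10–13, β 13–30 Hz), giving 480 features per epoch.

Around that core the package provides:

* zero-phase Butterworth preprocessing, decimation to 125 Hz, epoching at
  2–14 s windows (`preprocess_recording()`);
* a synthetic EEG cohort generator with planted band-specific phase-lag
  coupling, noise, and a zero-lag volume-conduction confound
  (`simulate_cohort()`);
* combined cleaning and resampling (CCR) for class imbalance
  (`ccr_resample()`);
* gradient-boosted-tree classification (xgboost by default; LightGBM /
  CatBoost honored when installed) with tree-structured Parzen estimator
  hyperparameter search over fixed printed spaces (`boost_spec()`,
  `tpe_search()`);
* recursive feature elimination with early stopping driven by
  fold-averaged importances (`rfe_early_stop()`);
* repeated stratified cross-validation with multiclass macro metrics —
  accuracy, F1-macro, G-mean-macro, Cohen's kappa — and a window-length
  sweep (`repeated_stratified_cv()`, `time_window_sweep()`);
* attribution of selected features to rhythms and brain lobes
  (`rhythm_distribution()`, `region_distribution()`).

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()`.

## Worked example

Simulate a small labeled cohort (severity expressed as graded beta-band
frontal–temporal coupling), extract PLI features at 10 s windows, evaluate
a boosted-tree grader, select features, and attribute them:

```r
library(eegrade)

cfg <- sim_config(n_per_class = c(3, 3, 3, 3), duration_s = 60,
                  edges = planted_edges(kappas = c(0, 0.3, 0.6, 0.9)),
                  seed = 42)
report <- run_pipeline(sim = cfg, window_s = 10, seed = 42)
report
#> <grading_report> window 10 s | xgboost
#>   all 480 features: accuracy 0.899 +/- 0.095
#>   optimal subset (12 features): accuracy 0.921 +/- 0.056

rhythm_distribution(report$rfe$best_features)
#> # A tibble: 4 × 2
#>   band       n
#>   <chr>  <int>
#> 1 theta      1
#> 2 alpha1     5
#> 3 alpha2     1
#> 4 beta       5
```

Reading the output: 72 ten-second epochs (6 per subject) are graded by
repeated stratified 5-fold cross-validation; with all 480 PLI features the
grader recovers the four severity levels with ~90% accuracy, recursive
elimination compresses the feature set (here to 12 features) and improves
accuracy, and the selected connectivity features concentrate in the beta
band (tied top band in this run — single runs at this small scale have
real variance). `region_distribution()` similarly shows the selected
edges' endpoints concentrating on frontal and temporal electrodes.

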