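# eegavalanche

Neuronal-avalanche and event-related-potential (ERP) analysis for
multichannel EEG cohort studies, with a first-class synthetic-data module.

The package addresses a three-cohort electrophysiology design around
post-viral "brain fog": cohort A (post-infection, with the cognitive
phenotype), cohort B (post-infection, without it) and cohort C
(never-infected controls), recorded with a 256-electrode geodesic net at
250 Hz. It provides the full analysis chain for two questions:

* **Do task-evoked responses differ?** Per-cohort ERP grand averages on the
  26 posterior cognitive electrodes for three paradigms (face recognition,
  digit span, task switching), ranked by the smallest cross-cohort
  zero-lag cross-correlation — the least-correlated electrodes are where
  cohort ERP shapes diverge most.
* **Can cohorts be classified from resting-state dynamics?** Each 5-minute
  eyes-closed recording is reduced to two neuronal-avalanche features and
  classified with linear discriminant analysis (LDA) over five binary
  cohort comparisons, with stratified 70/30 splitting, k-fold
  cross-validation and sensitivity/specificity/PPV/NPV reporting.

## The avalanche features

After the resting-state cleaning chain (1 Hz high-pass, scalp-channel
selection at projected radius ≤ 0.5 leaving 137 of 256 channels, 45–55 Hz
line-noise removal, decimation to 125 Hz, common-average re-reference,
40 Hz low-pass), each channel is z-scored and events are detected as
excursions beyond ±2.7 SD (one event per excursion, at its extremum).
Events are binned at Δt = 24 ms (3 × 8 ms, i.e. 3 samples at 125 Hz) and
maximal runs of non-empty bins, bounded by empty bins, form avalanches.
Two features summarise the dynamics:

* the size-distribution exponent **α**, from the discrete power law
  P(s) ∝ s^α fitted by zeta-normalised maximum likelihood
  (α ≈ −3/2 at criticality), and
* the branching parameter **σ**, the mean over avalanches of
  second-bin/first-bin event counts (duration-1 avalanches contribute 0);
  σ = 1 marks critical dynamics and indexes the excitation–inhibition
  balance.

Reference values measured on controls at 24 ms bins — α = −1.5336,
σ = 1.1023 — serve as the defaults of the synthetic cohort design and as
the generative values of the parameter-recovery checks.

## Worked example

Simulate critical branching cascades, render them into a noisy 137-channel
resting recording, clean it with the classification pipeline and extract
the feature vector:

```r
library(eegavalanche)

cascades <- simulate_branching_cascades(n_channels = 137, sigma = 1.0,
                                        n_avalanches = 400, seed = 42,
                                        max_duration = 30)
render <- render_resting_recording(cascades, fs = 250, duration_s = 150,
                                   seed = 43)
clean <- classification_preprocess(render$recording)
compute_features(clean)
#> <avalanche_features> alpha = -1.5265, sigma = 1.0100 (402 avalanches, 24 ms bins)
```

The generative state (σ = 1, critical) is recovered: σ̂ = 1.01 and
α̂ = −1.53 ≈ −3/2. The bin-width sweep shows why 24 ms is the working
width — 8 ms bins (one sample) fragment cascades into single events
(σ̂ ≈ 0), while overly coarse bins merge distinct cascades and inflate σ̂:

```r
sweep_bin_widths(clean, detection_config())[c(1, 3, 6), ]
#>   multiplier bin_width_ms alpha   sigma n_avalanches
#> 1          1            8 -1.66 0.00227         2200
#> 3          3           24 -1.53 1.00995          402
#> 6          6           48 -1.53 1.36142          400
```

Classify the default synthetic cohort design (120 subjects; cohorts A and B
carry a branching parameter 0.15 below the controls):

```r
feats <- simulate_cohort_features(default_cohort_specs(),
                                  n_cascades = 1500, seed = 305)
rep5 <- run_comparisons(feats, seed = 306)
rep5$test
#>       task sensitivity specificity   ppv   npv n_test
#> 1 A&B vs C       1.000       1.000 1.000 1.000     36
#> 2 B&C vs A       0.333       0.792 0.444 0.704     36
#> 3   A vs B       0.750       0.500 0.600 0.667     24
#> 4   A vs C       1.000       1.000 1.000 1.000     24
#> 5   B vs C       1.000       1.000 1.000 1.000     24
```

Tasks that separate the effect-bearing groups (A&B vs C, A vs C, B vs C)
classify perfectly at this effect size and sample count, while the tasks
that contrast identically generated cohorts (A vs B, and B&C vs A whose
positive class sits inside the pooled group) hover at chance — the designed
calibration behaviour. A full end-to-end run (ERP ranking CSVs, features,
both classification reports, JSON manifest) is
`run_pipeline(run_config(seed = 1))`, or from the shell:

```sh
Rscript scripts/run_demo.R --seed 1 --out demo_run
```

## Package layout

* `R/synth-*.R` — schedules, branching cascades, signal rendering, cohort
  datasets (the synthetic study design)
* `R/preprocess.R`, `R/filters.R` — the two cleaning pipelines;
  second-order-section Butterworth filtering
* `R/avalanche.R` — detection, binning, segmentation, the α MLE and the σ
  estimator
* `R/erp.R` — grand averages, smoothing, cross-correlation ranking
* `R/classify.R` — shrinkage LDA, splits, cross-validation, the five
  comparison tasks
* `R/io.R` — recording/montage/schedule I/O and `run_pipeline()`
* `vignettes/eeg-avalanche-methods.Rmd` — models, conventions and design
  choices in detail
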