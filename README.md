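# gaitfog

Spatiotemporal gait parameters and freezing-of-gait (FoG) screening from a
single knee-worn triaxial accelerometer.

FoG — the episodic inability to step forward in Parkinson's disease — is
normally quantified in a motion-capture laboratory. `gaitfog` implements a
wearable alternative for clinicians and movement-science researchers: from
one 32 Hz, ±8 g accelerometer at the knee it

1. detects **initial contacts** (heel strikes) from the minima of the
   Gaussian-smoothed vertical acceleration (orientation-corrected,
   zero-phase Butterworth-filtered, smoothed by integration, and
   differentiated with a Gaussian continuous-wavelet kernel);
2. estimates **five gait parameters** via an extended inverted-pendulum
   model — step time `IC(i+1) − IC(i)`, stride time `IC(i+2) − IC(i)`,
   step length `KG · 2·√(2·Wp·D − D²)` (with `Wp = 0.34` m the sensor
   height, `KG = 4` a generic knee-to-centre-of-mass factor, and `D` the
   per-step vertical excursion from double integration), stride length
   `2 × step length`, and walking speed (mean step length / mean step
   time);
3. assembles a **14-feature descriptor** (the five parameters, per-axis
   standard deviations, zero-lag cross-axis correlations, per-axis
   harmonic ratios) and augments it with all 14 PCA scores into a
   28-dimensional vector;
4. validates estimates against a reference system (per-subject **mean
   error rate** and **Pearson correlation**) and screens FoG vs no-FoG
   with four classifiers (RBF-SVM, k-NN, decision tree, naive Bayes)
   under a stratified 70:30 protocol repeated over seeded simulations.

Because no recording set is distributed with the method, the package
includes a first-class synthetic-data module (`simulate_walk()`,
`simulate_feature_cohort()`, `simulate_study()`) that generates
ground-truthed pendulum-kinematic walks and labelled cohorts for every
stage.

## Worked example

Process one synthetic walk end to end:

```r
library(gaitfog)

w <- simulate_walk(n_steps = 30, seed = 42, subject_id = "P01")
res <- process_recording(w$recording)
glance(res$gait)
#> # A tibble: 1 × 8
#>   subject_id side  avg_step_time avg_stride_time avg_step_length
#> 1 P01        left          0.551            1.10           0.444
#>   avg_stride_length walking_speed n_steps
#>               0.887         0.805      30
```

The walk was generated with ~0.55 s steps and ~5 mm vertical excursion;
the recovered step time (0.551 s vs true 0.5514 s) is exact to the sample,
and the step length (0.444 m vs true 0.456 m) is within 3%. Walking speed
is their ratio.

A full 51-subject study — simulate, validate against the generator truth,
classify:

```r
study <- simulate_study(n_fog = 36, n_nofog = 15, seed = 1, n_steps = 25)

val <- run_validation_pipeline(study)
val$report
#> Concurrent-validity report (51 subjects)
#>          parameter mean_error sd_error pearson_r n_subjects
#>      avg_step_time     0.6587   0.9179    0.9922         51
#>    avg_stride_time     0.3583   0.4712    0.9979         51
#>    avg_step_length     5.3278   3.7076    0.9194         51
#>  avg_stride_length     5.3278   3.7076    0.9194         51
#>      walking_speed     5.1272   3.8451    0.9668         51

features <- extract_study_features(study)
reports  <- run_simulations(features, features$label, base_seed = 1)
glance(reports)
#> # A tibble: 4 × 5
#>   classifier_kind n_simulations mean_accuracy mean_sensitivity mean_specificity
#> 1 svm_rbf                    10          86               92.7             67.5
#> 2 knn                        10          88.7             97.3             65
#> 3 dt                         10          82.7             85.5             75
#> 4 nb                         10          92               90               97.5
```

Mean error is the per-subject absolute percentage deviation from the
reference, averaged over subjects (here ≤ 5.3% per parameter); `pearson_r`
is the between-system correlation of per-subject values. Classifier rows
are means over ten stratified 70:30 splits, with FoG the positive class
(sensitivity = detected FoG fraction, specificity = detected no-FoG
fraction). `autoplot()` methods draw the aligned signal with detected
contacts, estimate-vs-reference scatter panels, and per-simulation
accuracy boxplots; `tidy()`/`glance()` return every result as a tibble.

A thin command-line wrapper with `simulate`, `validate` and `classify`
subcommands is installed at `system.file("scripts/gaitfog", package =
"gaitfog")`.

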