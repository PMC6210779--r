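---
title: "From knee-worn accelerometry to gait parameters and FoG screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From knee-worn accelerometry to gait parameters and FoG screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfog)
```

## The problem

Freezing of gait (FoG) is an episodic inability to step forward that
affects many people with advanced Parkinson's disease and is strongly
linked to fall risk. Assessing it objectively normally requires a
camera-based motion-capture laboratory. This package implements the
alternative: a single low-cost triaxial accelerometer worn at the knee
(about 0.34 m above the ground, sampled at 32 Hz, ±8 g range), from which
five spatiotemporal gait parameters are estimated, a 28-dimensional gait
descriptor is built, and FoG / no-FoG status is screened with standard
classifiers.

The pipeline has four stages, each exposed as ordinary functions that take
a data frame and return a tibble:

1. **Signal conditioning** — `read_recording()`,
   `realign_to_horizontal_vertical()`, `lowpass_filter()`.
2. **Event detection** — `smooth_by_integration()`,
   `gaussian_cwt_derivative()`, `detect_initial_contacts()`
   (or the one-call `find_initial_contacts()`).
3. **Gait parameters** — `vertical_excursion()`, `step_length()`,
   `summarize_gait()`.
4. **Features, validity and classification** — `assemble_features()`,
   `pca_augment()`, `validation_report()`, `run_simulations()`.

## The model

### Initial contacts

Heel strikes (initial contacts, ICs) are the minima of the smoothed
vertical acceleration. The raw signal is first rotated so its
recording-mean acceleration vector — the gravity direction during
quasi-static wear — lies along the vertical axis, and 1 g is subtracted.
A fourth-order Butterworth low-pass at 15 Hz (applied forward and
backward, so zero phase) removes high-frequency content without shifting
event timing. The filtered vertical acceleration is smoothed by cumulative
trapezoidal integration (with linear detrend) and differentiated with a
first-derivative-of-Gaussian kernel — a Gaussian continuous wavelet
transform. Since differentiation undoes the integration, the chain is
equivalent to Gaussian-smoothing the acceleration itself; its minima mark
the ICs.

### Spatiotemporal parameters

With ICs \(t_1 < t_2 < \dots\) (alternating feet):

* step time \(= t_{i+1} - t_i\), stride time \(= t_{i+2} - t_i\);
* step length \(= K_G \cdot 2\sqrt{2 W_p D - D^2}\), the inverted-pendulum
  chord for a pendulum of height \(W_p\) (sensor height, 0.34 m) whose apex
  falls by \(D\), scaled by a generic factor \(K_G = 4\) that maps the knee
  position to the centre of mass without per-subject calibration;
* stride length \(= 2 \times\) step length; walking speed \(=\) mean step
  length / mean step time.

\(D\) is the peak-to-trough range of the displacement obtained by
double-integrating the vertical acceleration between two consecutive ICs.

### Features and classification

The per-subject descriptor has 14 entries (in fixed order): the five
parameter averages, the per-axis standard deviations
\(\sigma_x, \sigma_y, \sigma_z\), the zero-lag cross-axis correlations
\(S_{xy}, S_{xz}, S_{yz}\), and per-axis harmonic ratios (even/odd
harmonic-amplitude sums at multiples of the stride frequency; the
mediolateral axis uses the reciprocal orientation). PCA on the
standardised features yields 14 components, all of which are appended to
the originals — a 28-dimensional vector. Four classifiers (RBF-SVM, k-NN,
decision tree, Gaussian naive Bayes) are compared under a stratified
70:30 train/validation split repeated over seeded simulations, reporting
accuracy, sensitivity and specificity with FoG as the positive class.

## Tunable parameters

| Config key | Default | Unit | Why |
|---|---|---|---|
| `sampling_rate` | 32 | Hz | target sensor's rate |
| `sensor_height`, `pendulum.Wp_m` | 0.34 | m | knee placement |
| `pendulum.KG` | 4 | — | generic knee-to-CoM factor |
| `filter.order` / `filter.cutoff_hz` | 4 / 15 | — / Hz | gait content sits below ~10 Hz; 15 Hz is deliberately permissive |
| `cwt.scale` | `"auto"` | samples | `fs / (6 f_step)`, cadence-adaptive (below) |
| `detect.prominence_frac` | 0.5 | × sd | amplitude-scale-invariant threshold |
| `detect.min_separation_s` | 0.25 | s | shortest physiological step |
| `detect.ic_guard` | 0 | samples | impact-artifact interpolation half-width |
| `features.n_harmonics` | 20 | — | truncated below Nyquist (~17 usable at 32 Hz) |
| `classify.train_fraction` / `n_simulations` | 0.7 / 10 | — | split protocol |

## Numerical choices

Several choices matter numerically and were settled by measurement
against the generator's closed-form ground truth (the same checks run in
the test suite):

* **Gravity removal is absolute.** The rotation aligns the mean
  acceleration with the vertical, but exactly 1 g is subtracted rather
  than the mean-vector norm. During walking the mean contains a genuine
  dynamic component; absorbing it into the gravity estimate injects a
  constant bias into every step segment, and over a single step a constant
  bias is *indistinguishable* from the pendulum arc (both integrate to a
  symmetric parabola). An absolute zero is therefore a precondition for
  unbiased excursion estimates.
* **Drift correction preserves the arc.** The default rule in
  `vertical_excursion()` removes only the velocity integration constant
  (its mean). Removing a full linear velocity trend — the other common
  rule, available as `drift = "velocity_linear"` — provably removes ~92%
  of a half-period arc and is kept for signals whose zero level is
  untrusted. Similarly, the displacement is *not* linearly detrended in
  the default rule: a sine has a non-zero linear component over a single
  period, so detrending removes genuine excursion (~5% for a full-period
  sinusoid).
* **Impact transients are interpolated out, minimally.** Linear filtering
  preserves the area of the heel-strike transient, so it otherwise adds a
  velocity step comparable to the arc velocity to every integrated
  segment. Only the IC sample itself is replaced by interpolation
  (`ic_guard = 0`); wider windows measurably eat into the arc.
* **The smoothing scale follows cadence, from below.** The Gaussian scale
  is `fs / (6 f_step)` with `f_step` the periodogram argmax in the
  0.5–3 Hz walking band. A periodic train of contact responses flattens
  once the Gaussian width approaches half the contact spacing
  (`fs / (2 f_step)` is already degenerate), and the timing jitter of a
  smoothed transient under noise grows with the width (the dip amplitude
  falls like \(1/\sigma\), the noise only like \(1/\sqrt{\sigma}\)).
* **The prominence threshold uses the interior sd.** The convolution's
  edge regions (one kernel half-width) carry large transients; including
  them in the reference sd silently rejects genuine contacts. Edge-region
  minima are excluded for the same reason.
* **Zero-phase filtering is reflection-padded.** Plain forward-backward
  filtering from a zero state distorts the series ends; odd-reflection
  padding with offset correction makes constants pass exactly.
* **Conflicting minima** within `min_separation_s` are resolved
  deterministically: deeper wins, ties to the earlier index.
* **PCA determinism:** loadings are sign-fixed (largest-magnitude loading
  positive) and the transform is frozen on the training fold of each
  simulation, so no statistics leak from validation subjects.

## The synthetic-data generator

No public recording set accompanies the method, so `simulate_walk()`
produces ground-truthed walks: per step the sensor's vertical displacement
follows a half-sine arc of height \(D\) (drawn per step), giving an
analytic acceleration; a one-sample negative transient of 0.5 g marks each
IC; gravity, a mounting tilt, and white noise are added. The defaults —
0.55 ± 0.02 s steps, \(D\) = 5 ± 1 mm, 5° tilt, 0.02 g noise, 30 steps
with 1.5 s of quiet standing at each end — match the reported walking
scale of advanced-PD cohorts (step times around 0.53–0.57 s) and the
stated sensor geometry. `simulate_feature_cohort()` draws labelled
14-feature vectors from a correlated multivariate normal with the FoG
class shifted toward impaired gait (longer times, shorter steps, lower
speed, less harmonic symmetry), and `simulate_study()` builds a full
36 FoG / 15 no-FoG cohort of recordings with class-separated walking
characteristics.

What the generator does *not* emulate: actual freezing episodes
(trembling-in-place spectra), turns, double-support dynamics, soft-tissue
resonance, or sensor drift. Passing tests therefore demonstrate that the
implementation recovers the model's own quantities under controlled
conditions — they are not clinical validation on real data.

The half-sine arc was chosen over a biomechanically richer waveform
precisely because its second derivative is closed-form, which makes the
double-integration estimator testable against an exact oracle.

## Design decisions on open points

* Left- and right-knee recordings are processed independently and their
  summaries averaged (`combine_gait_summaries()`), since the fusion rule
  is not fixed by the method; signal-level features are likewise averaged
  per subject when both sides exist.
* Harmonic ratios and cross-correlations are computed on the raw sensor
  axes (the descriptor names raw x/y/z); the knee sensor's x and z axes
  are treated as progression/vertical (even/odd) and y as mediolateral.
* The stratified split rounds `0.7 × n_class` half-up per class. For the
  36/15 cohort this gives a 36-subject training and 15-subject validation
  fold. No per-class rounding rule reproduces a 10 + 5 validation
  composition from these sizes, so the totals rather than the composition
  are matched.
* Classifier hyperparameters are conventional defaults (SVM cost 1 and
  kernel width 1/28 on standardised features; k = 5; Gini tree without
  depth limit; Gaussian naive Bayes), exposed through `hyperparams`.
* What varies across repeated "simulations" is the seeded stratified
  split (and any stochastic model internals), re-seeded `base_seed + s`.
* Reported error rates use the absolute percentage deviation per subject;
  the signed variant is available (`signed = TRUE`).

## Problem sizes

The test suite and the acceptance script run entirely on generated data
at deliberately compact sizes — 30-step walks on a 6 × 4 grid of step
times (0.45–0.70 s) and excursions (2–15 mm), 20 noisy replicates, and a
51-subject study (36 FoG / 15 no-FoG, 25 steps each, 10 split
simulations) — chosen so the whole analysis replays from scratch in well
under a minute while still covering the method's operating range.

## Known limitations

* A constant accelerometer bias within a step cannot be separated from
  pendulum motion by any per-step drift rule; accuracy therefore depends
  on the absolute gravity calibration of the sensor.
* With a 32 Hz sensor, step-time resolution is one sample (31.25 ms), and
  near-Nyquist filtering (15 Hz cutoff) attenuates very little — the
  filter matters more at higher sampling rates.
* The imbalanced 36/15 cohort makes raw accuracy an optimistic metric: a
  majority-class predictor already scores ~71%; sensitivity/specificity
  should be read alongside it.
* `KG = 4` is generic; individual calibration (intentionally avoided
  here) would change absolute step lengths but not the relative
  comparisons the classifier uses.

## Example

```{r example, eval = FALSE}
study <- simulate_study(n_fog = 36, n_nofog = 15, seed = 1)
val <- run_validation_pipeline(study)
tidy(val$report)

features <- extract_study_features(study)
reports <- run_simulations(features, features$label, base_seed = 1)
glance(reports)
autoplot(reports)
```
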