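---
title: "Methods: multimodal physiological analysis of emotional valence"
author: "valphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal physiological analysis of emotional valence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valphys)
```

# The problem

Affective valence — the pleasant-versus-unpleasant axis of the dimensional
model of emotion — leaves traces in both the central nervous system (EEG) and
the autonomic nervous system (heart-rate variability, skin temperature).
`valphys` implements a complete analysis chain for studies in which subjects
watch emotionally positive and negative video clips while EEG, ECG and wrist
temperature are recorded: per-modality feature extraction, nonparametric
condition statistics with gender splits, wrapper feature selection, and
valence classification evaluated both within subjects (subject-dependent, SD)
and across subjects (subject-independent, SI, leave-one-subject-out).

Because raw recordings of such studies are rarely shareable, the package
ships a synthetic-data generator that emulates the statistical structure of a
24-subject study (16 men, 8 women; 14 clips of 43–78 s per subject, half
positive and half negative, interleaved with 30 s baselines). Every analysis
stage is exercised end-to-end against this generator; the planted effects and
their magnitudes are the package's study conditions, fixed once and
documented below.

# The synthetic cohort

`generate_dataset(study_design(), effect_model())` draws, per subject:

* **Valence/arousal ratings** from truncated normals on [1, 9] with class
  means 7.51 (s.d. 1.6) and 2.91 (s.d. 0.98) for positive and negative
  valence, and 3.76 / 5.47 for arousal — the summary statistics of the
  emulated study. Ratings are exposed for the correlation analysis; no
  arousal-driven physiological effect is planted, since the emulated study
  reported arousal differences but tied no physiological finding to them.
* **Inter-beat intervals** per trial from an AR(1) process
  (coefficient 0.8, marginal s.d. 25 ms around a subject-level base interval
  ~ N(850, 50) ms) plus respiratory (0.25 Hz, 20 ms), low-frequency
  (0.08 Hz, 15 ms) and very-low-frequency (0.02 Hz, 10 ms) oscillations, so
  that every time-domain, frequency-domain and Poincaré measure is
  nondegenerate. Raw ECG can additionally be rendered as one
  Gaussian-derivative QRS wavelet (80 ms wide, 1 mV) per beat on the sample
  grid, which the detector must recover within one sample.
* **Skin temperature** at 1 Hz: a mean-reverting drift (stationary
  s.d. 0.1 °C) around a subject baseline ~ Uniform(26.1, 28.1) °C, white
  sensor noise (0.05 °C), sparse ±3–8 °C spike artifacts (rate 1/300
  samples) that exercise the outlier rule, a task-evoked rise of 1.72 °C
  during stimulation, and the planted negative-valence shift.
* **EEG band powers** directly at the feature level (synthesising realistic
  64-channel raw EEG is a non-goal; the raw-EEG path is exercised on small
  fixtures). Log-power for each of the 24 region-band features decomposes as
  a band-dependent base level, a subject offset (s.d. 0.3), a valence
  response, trial noise (s.d. 0.2) and window noise (s.d. 0.3).

## Planted effects and their defaults

| Effect | Default | What it emulates |
|---|---|---|
| `nn50_male_shift` | 5 | more large successive-IBI differences on positive trials, men only |
| `sd2_female_shift` | 20 ms | higher long-term IBI variability (SD2) on negative trials, women only |
| `temp_neg_shift` | 0.08 °C | warmer skin on negative trials, carried by women |
| `temp_task_shift` | 1.72 °C | stimulus-versus-baseline temperature rise |
| `eeg_asym_shift` | 0.3 | population-consistent lateralization: prefrontal left-up for positive valence, occipital reversed |
| `eeg_subject_shift` | 1.2 | each subject's own response magnitude per feature |
| `subject_heterogeneity` | 0.3 | s.d. of the per-subject effect multiplier ~ N(1, ·) |
| `eeg_heterogeneous` | `TRUE` | random per-subject, per-feature response signs |

The temperature numbers come directly from the emulated study's reported
means (28.767 / 28.847 / 27.087 °C for positive / negative / baseline): the
baseline range is centred on 27.1 °C, the task shift is their difference,
and the negative shift is the reported negative-minus-positive gap,
attributed to women because only the women's split reached significance
there. The HRV shifts have no reported magnitudes; 5 extra NN50 counts and
20 ms of SD2 are moderate effects — roughly one within-group standard
deviation — that a study of this size can detect but not trivially. The EEG
defaults put the package in the regime the emulated study actually observed:
near-perfect SD classification together with chance-level SI transfer, which
requires each subject's response to dwarf the population-consistent
component and to vary in sign across subjects.

Two generator subtleties deserve note. First, the NN50 effect is injected
as zero-sum adjacent interval-pulse pairs (+100/−100 ms), with the expected
pair count calibrated by quadrature against the model's baseline probability
of a >50 ms successive difference, and with all stochastic components shrunk
so the expected SD2 is unchanged — a naïve pulse injection leaks the planted
short-term effect into the long-term measures and destroys effect
specificity. Second, the SD2 effect is injected as a slow (1/30 Hz)
oscillation whose amplitude is solved analytically from the model's expected
SD2, leaving SD1 and NN50 essentially untouched.

# HRV measures

The 19 measures are computed from artifact-corrected inter-beat intervals:
mean and median RR, SDNN, RMSSD, NN50, pNN50 (time domain); total power and
VLF / LF / HF as absolute power (ms²) and percentages, LF and HF in
normalised units, and LF/HF (frequency domain; bands 0.003–0.04,
0.04–0.15, 0.15–0.4 Hz); SD1, SD2, SD1/SD2 (Poincaré). Conventions:

* **Population variances** (divide by *n*) for SDNN, SD1 and SD2, so the
  identity SD1² + SD2² = 2·SDNN² holds exactly; this is asserted to 1e-12
  in the tests.
* **pNN50 = NN50 / (n − 1)**: the proportion of successive *pairs*, the
  standard pairs convention.
* **VLF lower bound 0.003 Hz** (configurable): the definitional band table
  is taken as authoritative over the looser "0–0.04" phrasing that
  sometimes accompanies it.
* **Spectral estimation by Lomb-Scargle periodogram** evaluated directly on
  the unevenly spaced beat times — no resampling scheme has to be invented
  for the uneven tachogram. The periodogram is rescaled so that its
  integral over the scanned range equals the tachogram variance, giving
  absolute powers in ms². A cubic-spline-resample-plus-Welch alternative is
  available behind `method = "welch"`. Trials are 43–78 s, well below the
  5-minute convention for frequency-domain HRV: series shorter than 30 s
  are flagged low-confidence, and geometric HRV methods (which need ~20
  minutes) are out of scope entirely.
* **R-peak detection** (the upstream tooling's algorithm is unpublished):
  the 10 Hz-high-passed signal is squared, integrated over a moving 80 ms
  window, thresholded at a rolling mean + 2 s.d. (2 s window), and each
  candidate region's beat is localised by the energy centroid of the
  squared signal over a fixed ±40 ms window, with a 200 ms refractory rule.
  On synthesized ECG the full synthesize → detect → interval round trip is
  accurate to one sample.
* **Artifact rule** (the upstream tooling's criterion is likewise
  unpublished): intervals deviating more than 25% from the median of the 5
  preceding clean intervals are flagged — a Berntson-style criterion with a
  configurable threshold — and replaced by shape-preserving piecewise-cubic
  (PCHIP) interpolation over the clean neighbours. A classical cubic spline
  can overshoot beyond the neighbouring clean beats (on the fixture
  [800, 810, 400, 805, 795] ms it reconstructs ~811 ms, outside the
  neighbours); PCHIP cannot, which is why it is the default, with
  `method = "cubic"` available. Trials with more than 20% flagged intervals
  are rejected with a quality error rather than silently corrected.

# EEG features and asymmetry

Raw EEG is band-passed 0.5–45 Hz (zero-phase Butterworth) and re-referenced
to the common average; a pluggable artifact hook is provided but empty,
since component-based artifact rejection is interactive by nature and the
synthetic data are clean. Band powers are Welch estimates integrated over
Alpha 8–12, Beta1 12–20, Beta2 20–30 and Gamma 30–45 Hz — conventional
boundaries consistent with the 45 Hz low-pass, configurable because the
emulated study inherited (and did not print) its exact definitions. The
same applies to the electrode-region map: standard 10/10 neighbourhoods
(e.g. PF-left = {Fp1, AF3, AF7}) are defaults, not ground truth.

The 20 model features are specific region-band combinations (all four bands
prefrontally, narrower selections centrally, parietally and occipitally);
four auxiliary homologous left-side powers complete the 9 lateralized pairs
entering the asymmetry analysis. The asymmetry index of a pair is
AI = (right − left) / (right + left), in [−1, 1], antisymmetric under
hemisphere exchange and invariant under common rescaling; midline regions
never form pairs. For each pair the package reports Mann-Whitney
comparisons of AI between valence conditions and of raw left-versus-right
power within each condition, in SD and SI modes.

By default one feature vector is produced per 4 s window (50% overlap)
within each trial, multiplying within-trial observations; windows of one
trial are never split across cross-validation folds. A one-window-per-trial
mode is available. The SD scores reported by studies of this design are
only reachable with window-level observations — at 14 trials per subject a
trial-level SD fold simply has too few units — which is why window mode is
the default.

# Temperature

Traces are segmented into 28 s windows (the first 28 s of each clip, offset
configurable, and each baseline period). Samples strictly more than
3 scaled MADs (1.4826·MAD) from the segment median are replaced by the mean
of the non-outlier samples, iterated to a fixed point so the operation is
idempotent. The strict inequality makes the MAD = 0 case behave sensibly: a
constant segment flags nothing, a constant-plus-spike segment flags exactly
the spikes. Condition statistics (positive vs negative vs baseline) are
Mann-Whitney tests on the pooled cleaned samples, SD or SI, with gender
filters.

# Statistics

All group comparisons are two-sided Mann-Whitney tests: the one-sample
Kolmogorov-Smirnov check (standardised sample against the standard normal)
is provided as the gate that motivates the nonparametric stance. The exact
U distribution is used for tie-free samples up to 50 per group; otherwise
the normal approximation with tie and continuity corrections. The exact
path is verified in the tests against full enumeration of all label
arrangements for group sizes up to 6. No multiple-testing correction is
applied by default — the emulated study reports raw p-values — and
`p.adjust`-based correction is a one-liner away for users who want it.
Feature-rating correlations are Spearman (Pearson behind a flag), per
subject (SD) or pooled (SI).

Two statistical caveats are documented deliberately. Pooled SI tests on
window- or sample-level observations treat clustered data (windows within
trials, samples within subjects) as independent and are therefore
anti-conservative; the emulated study's extremely small pooled p-values
should be read with the same caution. And with balanced labels inside each
cluster the same clustering can make pooled tests conservative instead —
the package's calibration tests use trial-level observations, where the
nominal level genuinely holds.

# Feature selection

`anneal_select` is a Metropolis search over feature subsets scored by
cross-validated positive-class F1: better states are always accepted, worse
ones with probability exp(Δ/T), the temperature decaying geometrically.
Defaults — initial temperature 0.1 in F1 units, cooling rate 0.95, 500
steps (the first being the evaluation of the initial state, a random half
of the features), single-bit-flip neighbourhood — converge on a 19-feature
space in seconds. The same cross-validation folds are reused for every
subset inside a run, so subset comparisons are free of fold noise; ties in
best score break toward the smaller subset; subject-disjoint folds give the
subject-independent objective used in the pipeline. The whole run is
reproducible from its seed, and the running best is non-decreasing by
construction.

# Classification

KNN (k = 5, Euclidean) and QDA over configurable modality sets: the 20 EEG
powers, NN50 (the HRV measure the emulated study carried into fusion), and
the per-trial mean cleaned temperature — 22 features in full fusion. Fusion
is a key join on subject × trial, with the trial's NN50 and mean
temperature broadcast to each EEG window: for per-trial scalar features
this is statistically equivalent to the signal-level resampling the
emulated study describes, and simpler. Subjects missing any modality are
dropped with a logged list.

Evaluation schemes, chosen where the emulated study is silent: SD is a
stratified 10-fold cross-validation over trials within each subject
(windows never straddle folds — the leakage that would otherwise inflate SD
scores is exactly what the grouped constraint prevents, and a probe test
verifies both directions); SI is leave-one-subject-out. Features are
z-scored with training-fold statistics only. F1 is the positive-class
harmonic mean (macro-F1 reported alongside), computed per held-out unit
(subject) and then averaged. QDA class covariances get automatic diagonal
shrinkage (coefficient 1e-3, with a warning) when singular — routine in
small within-subject folds where an integer feature like NN50 can be
constant within a class. Gender-split SI classification warns below 15
subjects per group, the commonly cited minimum for stable
subject-independent results; the emulated design's 8 women always trigger
it.

# Problem sizes in the test suite

The suite's heavier checks use: 1,000 random IBI series against brute-force
oracles; 500 null simulations for Mann-Whitney calibration (trial-level
observations, 7 vs 7); 100 generator seeds for gender-split effect
recovery; 20 seeded annealing restarts for planted-feature recovery; and
two complete 24-subject pipeline runs compared byte for byte. These sizes
are the package's own choices balancing Monte-Carlo error against runtime
on a single CPU.

# Limitations

The generator reproduces the *statistical structure* the analysis assumes —
planted mean shifts, subject heterogeneity, oscillatory IBI dynamics,
sensor spikes — not the physics of real recordings: no real QRS morphology
variation, ectopy, electrode artifacts, movement, circadian temperature
drift, or volume-conducted EEG sources. Passing tests therefore demonstrate
that the pipeline recovers what it claims from data with the assumed
structure, not that the assumed structure is what real recordings contain.
The band boundaries, region maps, windowing and artifact criteria mirror
common practice where the emulated study left them unstated, and all are
configurable rather than asserted as ground truth.
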