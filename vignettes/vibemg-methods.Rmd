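---
title: "vibemg: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vibemg: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what the
pipeline computes, which choices were genuinely open and how they were
resolved, what the synthetic generator does and does not emulate, and what
a green test therefore does and does not establish. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The measurement model

A coreless vibration motor (40–50 Hz, sub-millimeter stroke) on the skin
over a relaxed tibialis anterior drives a mechanical oscillation that a
bipolar surface EMG electrode records at 1,000 Hz. The recorded trace is
therefore dominated by a quasi-periodic carrier at the vibration frequency
plus harmonics, riding on broadband noise. The working hypothesis is that
venous occlusion changes tissue stiffness and hence the transmission of
the vibration, which shows up as a change — principally an upward shift —
in the dominant spectral peak, together with amplitude changes. The
pipeline never models this physiology; it only asks whether a classifier
can separate recordings made at different protocol stages (`T-1` baseline,
`T1`…`T8` post-occlusion every 20 min).

## Pipeline stages and the parameters that matter

| Stage | Parameter | Default | Units | Why |
|---|---|---|---|---|
| segmentation | window / hop | 400 / 200 | samples | protocol constants; 0.4 s windows at 1 kHz |
| spectrogram | FFT length / hop | 256 / 72 | samples | the two stated parameterizations (184-point overlap; windows 1–256, 73–328, 145–400) agree and are cross-checked in code |
| spectrogram | rows kept | 95 of 129 | bins of fs/256 Hz | one-sided spectrum of a 256-point transform has 129 rows; the lowest 95 (0–367 Hz) cover the carrier and harmonics |
| normalization | percentiles | 1st / 99th | — | robust min–max; values outside are clipped to [0, 1] |
| PCA | components | 25 | — | protocol constant; arranged in a 5 × 5 grid |
| CNN | filters / widths | 64; 4×4 and 2×2; FC 64 | — | protocol constants |
| training | batch / momentum / lr | 32 / 0.9 / 0.01 | — | protocol constants |
| training | max_epochs / patience | 200 / 20 | epochs | artifact choices; the reference protocol states no budget. Early stopping retains best-validation parameters |

Numerical conventions, fixed so results are bit-reproducible:

* **Hamming window**: symmetric, `0.54 − 0.46 cos(2πn/(N−1))`.
* **"Spectral intensity"**: magnitude (not power, not dB). Normalization
  removes global scale, so this choice only affects the shape of the
  percentile distribution.
* **Percentiles**: linear interpolation between order statistics
  (`quantile` type 7).
* **Degenerate normalization** (`lo == hi`): output all zeros.
* **PCA sign convention**: each component's largest-magnitude coordinate
  is made positive (eigenvectors are sign-ambiguous; golden tests need
  determinism).
* **Vectorization**: frequency-major (the 95 rows of time bin 1, then
  bins 2 and 3); the inverse is exported and tested.
* **Argmax ties** at prediction: lowest class index.

## Open interpretation points and how they were resolved

* **Normalization scope.** The protocol description is ambiguous between
  per-segment, per-stage and per-leg percentile fitting. We fit per leg,
  on training segments only, and apply the frozen statistics to that
  leg's validation/test segments — the only reading that is both
  per-leg and leakage-free. Refitting happens inside every CV rotation.
* **Convolution branch topology.** "64 filters that were 4 × 4 and 2 × 2
  in size" admits sequential or parallel readings. We use two parallel
  branches over the same 5 × 5 input (multi-scale, consistent with the
  myoelectric-interface lineage the architecture comes from): 4×4 → 2×2×64
  map, 2×2 → 4×4×64 map, concatenated to 1280 units after ReLU. Valid
  convolutions, stride 1, no pooling (none are described).
* **Fully connected sizing and dropout.** "Two fully connected layers …
  with a size of 64" is read as both layers having width 64; dropout
  (rate 0.5, inverted, training-only) applies to both.
* **Grid spiral.** Only the center rule ("most significant PC at the
  center") is specified. The remaining 24 cells are filled by a fixed
  outward clockwise spiral starting immediately right of center; the
  rank→cell table is exported (`pc_grid_layout`) and frozen by a golden
  test. Any fixed bijection would serve; freezing one makes experiments
  reproducible.
* **Fold stratification.** Whether the 10-fold split was stratified by
  stage is unstated; we stratify so every fold sees every class. Fold
  sizes still differ by at most one.
* **LOLO validation split.** The cross-leg protocol describes no
  validation set; we carve a seeded, label-stratified 90/10 split out of
  the 7 training legs for early stopping. The held-out leg never enters
  normalization, PCA, or training (asserted by a sentinel test).
* **`emg_feature_std`** uses the sample (n−1) standard deviation.

## The synthetic world

The generator is the package's own construction: the reference material
describes phenomena (a 40–50 Hz carrier; a post-occlusion upward peak
shift; heterogeneous per-leg responses) but no generative model. Each
stage trace is

y(t) = g_s · Σ_h a_h sin(h φ_s(t) + φ_h) · (1 + m sin(2π f_m t + φ_m)) + ε(t),

with instantaneous frequency f_vib + shift(s) + OU-drift. Defaults were
fixed a priori, before any cross-validation was run, and then frozen:

* `f_vib ~ U[40, 50]` Hz per leg (the measured motor range);
  harmonics (1, 0.3, 0.1); base amplitude 0.5 arbitrary units (absolute
  scale is irrelevant after normalization); noise sd 0.2.
* Stage shift schedule 0, 8.0, 8.8, …, 13.6 Hz: the baseline→`T1` jump of
  8 Hz is about two spectral bins (bin width 1000/256 ≈ 3.9 Hz), making
  the before/after contrast strongly separable, while consecutive
  post-occlusion stages differ by only 0.8 Hz.
* OU frequency drift, stationary sd 0.5 Hz, correlation time 5 s
  (motors drift with attachment pressure and skin condition). With
  0.8 Hz spacing and 0.5 Hz within-stage spread, an ideal 1-D Gaussian
  classifier confuses adjacent post-occlusion stages at ≈ 21% pairwise —
  chosen so that 9-class confusion concentrates off-diagonal among
  mid/late stages, while the hourly grouping (`T1`–`T4` vs `T5`–`T8`)
  errs mainly at its boundary, qualitatively matching the reported
  patterns.
* A mild monotone gain trend (1 → 1.17) and a slow amplitude modulation
  (depth 0.15 at 0.7 Hz); an optional per-stage multiplier
  (`pc_std_trend`) shapes segment-to-segment variance of the leading PC
  for the `emg_feature_std` statistic.

`generate_cohort` emulates the 8-leg design. `heterogeneity` scales all
leg-specific perturbations (carrier spread, gain jitter, a schedule
multiplier `1 + h·z`, `z ~ N(0, 0.3)`). With `shared_effect = FALSE`,
alternating legs swap the `T-1`/`T1` schedule entries, so the pooled
class-conditional feature distributions are symmetric across the cohort:
cross-leg transfer collapses while within-leg separability is untouched —
the dissociation between near-perfect within-leg accuracy and erratic
leave-one-leg-out accuracy that motivates the LOLO protocol in the first
place.

**A subtlety worth stating plainly.** In within-leg CV, training and test
segments come from the *same physical recording*. Any stage-specific
idiosyncrasy — such as the particular drift realization of that stage —
is therefore a legitimate (to the classifier) but non-generalizing cue.
For this reason the package's *null* world (used to verify chance-level
behaviour) switches the drift off and flattens gains: with drift on, a
"no-effect" leg still yields above-chance within-leg accuracy because the
classifier learns each stage's drift realization. This is not a bug; it
is the same mechanism that lets real within-leg CV overstate
generalization relative to LOLO.

## What a green test establishes — and what it does not

The synthetic suite establishes that the implementation is correct
(oracle-checked spectrograms and PCA, gradient-checked training,
leakage-safe CV) and that the pipeline has the expected statistical
behaviour on a world with the assumed structure (chance at null, high
power at a 2-bin shift, LOLO dissociation under cohort heterogeneity).
It does **not** establish that real vibration-EMG from an occluded limb
has this structure, nor reproduce the animal results: the original
recordings are not deposited, so the per-leg acceptance numbers are
computed on a clearly-labelled synthetic stand-in leg at the frozen
defaults and compared to the printed values only as a plausibility band.
Real EMG also contains artifacts the generator omits entirely: motion and
electrode artifacts, mains interference, non-stationary noise floors,
inter-electrode impedance drift, and any physiological EMG activity.

## Runtime scaling

Test and acceptance runs use a 60 s-per-stage stand-in leg (299 segments
per stage instead of 599) and reduced epoch budgets (30 epochs, patience
8); accuracies at this scale are statistically indistinguishable from the
full-duration runs for the quantities asserted, and the whole suite stays
within a CI-friendly budget on one CPU.

## Known limitations

* The CNN is implemented in base R (vectorized matrix algebra). It is
  deterministic and gradient-checked, but not performance-tuned for
  inputs much larger than the 5 × 5 grids it was designed for.
* `read_stage_table` accepts the published wide layout (CSV, or xlsx via
  `readxl`) and a long CSV; vendor binary EMG formats are out of scope.
* LOLO accuracy on heterogeneous cohorts is an inherently high-variance
  quantity (8 all-or-nothing outcomes); single-cohort means should be
  interpreted with its reported standard deviation alongside.
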