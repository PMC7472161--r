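---
title: "Designing symmetric wearable-EEG montages: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing symmetric wearable-EEG montages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegmontage)
```

## The design problem

Consumer EEG headsets carry a handful of electrodes, and where those
electrodes sit determines what a passive brain-computer interface (pBCI)
can decode. `eegmontage` implements a data-driven design procedure: given
an emotion-classification dataset and a sustained-attention dataset
recorded on a dense symmetric montage, it scores *every* hemispherically
symmetric electrode subset of a chosen size and reports

* the **emotion-specialized** montage — the subset maximizing mean
  four-class classification accuracy (valence–arousal quadrants HAHV,
  HALV, LAHV, LALV),
* the **attention-specialized** montage — the subset maximizing the mean
  largest absolute correlation between any EEG feature and a behavioral
  concentration index, and
* the **general-purpose** montage — the subset maximizing the
  generalized-configuration score, GCS = accuracy + |r|.

Symmetry means every lateral electrode appears with its mirror partner;
midline sites (Fz, Cz, Pz, Oz) are individually admissible. On the
default 32-channel montage (14 pairs + 4 midline) the admissible subsets
number 20, 176, 924 and 3276 for k = 2, 4, 6, 8 — a union of p pairs and
m midline channels with 2p + m = k, i.e.
$\sum_{2p+m=k} \binom{14}{p}\binom{4}{m}$ subsets. Enumeration order is
fixed (more pairs first, montage order within), which is also the
tie-break for equal scores.

## Preprocessing

The chain mirrors standard pBCI practice: common average reference,
per-channel baseline (mean) removal, a 6th-order zero-phase Butterworth
bandpass at 1–55 Hz (`signal::filtfilt`, so no group delay and a squared
magnitude response), segmentation into 1-s epochs with 50% overlap, and
*rejection* — never cleaning — of blink-contaminated epochs. Subjects
losing more than half their epochs are excluded (strictly greater than
the threshold).

Two notes on honest limitations. First, with the upper edge at 55 Hz the
filter attenuates a 60 Hz mains component by only ≈ 12.5 dB after the
forward–backward pass; the band keeps 50 Hz fully inside, and no notch is
applied by default (an explicit notch can be added upstream if mains
contamination matters). Second, the blink detector is a *contract*: any
function mapping an epoch to a flag can be plugged in. The default flags
an epoch when the peak-to-peak amplitude within any 200-ms sub-window on
the frontal channels (Fp1, Fp2, AF3, AF4 when present, otherwise all
channels) exceeds 100 µV with a rise-then-fall derivative signature. The
threshold is a configuration parameter; published blink detectors can be
substituted without touching the rest of the pipeline.

## The feature battery

Per epoch and channel set, the battery computes, over six sub-bands
(delta 1–4, theta 4–8, alpha 8–13, low beta 13–22, high beta 22–30,
gamma 30–50 Hz):

* **PSD** — mean $|X(f)|^2/N$ periodogram power over the DFT bins in
  `[low, high)`; no taper by default, matching the bare-DFT definition.
* **DASM / RASM** — difference and ratio of linear band powers at each
  interhemispheric pair (left minus right, left over right; a zero
  right-hemisphere power is epsilon-guarded with a warning).
* **Hjorth parameters** — activity (variance), mobility
  ($\sigma(\Delta x)/\sigma(x)$), complexity (mobility of the
  difference over mobility). A constant epoch returns (0, 0, 0) with a
  degeneracy flag rather than NaN.
* **Shannon entropy** — of the amplitude histogram over 16 equal-width
  bins spanning the epoch's range, natural log (range [0, ln 16]). The
  bin count is exposed in configuration.
* **Hurst exponent** — single-scale rescaled range,
  $\log(R/S)/\log N$, clipped to [0, 1.5] with a warning.
* **Kolmogorov complexity** — the signal is binarized at its median;
  the Lempel–Ziv (1976) phrase count $c(n)$ is normalized by
  $b(n) = n/\log_2 n$. On very long segments (attention windows) the
  quadratic parse is evaluated on the leading 2048 samples — the
  normalized estimate is stable in n and the cap keeps exhaustive
  searches affordable.
* **Higher-order cumulant** — the lag-(1, 2) third-order moment
  $\mathrm{E}[y_k y_{k+1} y_{k+2}]$ of the mean-removed epoch. The
  time-domain reading was chosen over a bispectral one; the lags are
  configurable.
* **CSP** — filter-bank common spatial patterns, one-vs-rest per class
  and band. Epoch covariances are trace-normalized and averaged per
  side; the generalized eigenproblem of the target-class covariance
  against the two-class sum is solved by whitening, and the
  largest- and smallest-eigenvalue filters are kept (2 per band), giving
  $f_p = \log\!\big(\mathrm{var}(Z_p)/\sum_i \mathrm{var}(Z_i)\big)$ and
  12 features per class over six bands. Rank-deficient covariances
  (e.g. the exact null direction created by common average referencing)
  are ridge-regularized with $\lambda = 10^{-6}\,\mathrm{tr}(C)/n_{ch}$
  and a warning.

Band-limited covariances for CSP are computed by DFT masking (ideal band
selection): by Parseval's relation the covariance of the brick-wall
band-filtered epoch equals the cross-spectral sum over the band's bins.
This makes per-fold CSP refits cheap enough for exhaustive searches.

For a channel set with $n_{ch}$ channels and $n_{pr}$ complete pairs the
battery width is
$6 n_{ch} + 6 n_{pr} + 6 n_{pr} + (3+4) n_{ch} + 12 \times 4$:
632 columns for the full 32-channel montage, 162 for
{CP1, CP2, O1, O2, F7, F8} — identities the test suite asserts exactly.

## Emotion evaluation

Features are ranked by the multi-class Fisher score
$\sum_c n_c(\mu_c-\mu)^2 / \sum_c n_c\sigma_c^2$ (affine-invariant; a
zero-within-variance separator ranks first) and at most 20 are kept.
Accuracy is estimated by repeated stratified cross-validation with a
linear SVM (C = 1, one-vs-one) by default; LDA and a decision tree are
available alternates.

Two choices deserve emphasis:

* **Folds split at the trial level.** Overlapping epochs from one trial
  are strongly autocorrelated; letting them straddle the train/test
  boundary inflates accuracy. Test-trial predictions are aggregated by
  majority vote over the trial's epochs. An epoch-level mode exists for
  diagnostics (e.g. the chance-level guard test).
* **Nothing is selected on test data.** CSP models and the Fisher
  ranking are recomputed inside every training fold. The "highest
  achievable" protocol of scoring every nested Fisher prefix on the test
  fold is available behind `optimistic = TRUE`, clearly labeled as
  optimistically biased — the package's tests demonstrate that on pure
  noise it inflates accuracy above chance while the leak-free default
  stays at 0.25.

## Attention evaluation

The behavioral concentration index over a window of trials is
$\mathrm{CONC} = (N_{CT} - N_{IT})/N_{TT}$ — correctly minus incorrectly
discriminated targets over total targets; distractor trials do not enter
the counts. Windows slide over trials (94 trials, 50% overlap by
default; 1316 trials yield 27 windows). Each feature is computed once
per window on the concatenation of the window's kept trials, and the
per-subject score is the largest absolute Pearson correlation (Spearman
optional) between any feature series and the CONC series; blink-rejected
trials leave both series simultaneously, keeping them aligned, and
windows without targets are dropped pairwise. CSP needs class labels the
attention task does not define; the default fits it on a median split of
the window CONC values (high versus low attention), a stand-in choice
noted as such.

## Search, GCS, and statistics

`optimize_montage()` evaluates every admissible subset of size k and
ranks by the design objective; GCS sums the two subject-averaged
metrics, so it lives in [0, 2] and exists once per configuration (no
per-subject distribution). Paired per-subject metrics across competing
designs are compared with a Friedman test followed, when significant at
0.05, by Bonferroni-corrected Wilcoxon signed-rank tests; a Lilliefors
(Kolmogorov–Smirnov) normality screen is reported alongside to justify
the rank-based choice. Consumer-headset presets (2, 5, 7 and 9
channels) ship as named channel sets for comparison runs; they are
best-effort mappings onto this montage, configurable, and carry no
guarantees about the actual commercial devices.

## The synthetic-data generator

Real emotion/attention corpora cannot ship with the package, so a
generator with known ground truth stands in:

* **Background**: independent per-channel $1/f$ Gaussian noise (FFT
  shaping, exponent 1, 20 µV), the canonical resting-EEG spectrum.
* **Emotion**: four classes differing in the amplitude of band-limited
  alpha noise added at chosen channels only (default F7/F8), multipliers
  0.2 / 1 / 2.2 / 3.5 around a 10 µV base with ±10% trial jitter;
  frontal biphasic blinks at Poisson times (100–300 µV) with positions
  recorded as ground truth.
* **Attention**: a smoothed-random-walk latent drift in [0, 1] drives
  both P(correct) = 0.25 + 0.7·drift and the amplitude of alpha noise at
  the coupling channels (default Fz/Pz). Each subject couples most
  strongly at one of the coupling channels, rotating across subjects —
  inter-individual variability that also makes the planted *set* (rather
  than any single member) the identifiable optimum of the max-|r|
  objective.

The generator emulates the structure of the real corpora — trial counts,
class balance, blink contamination, drifting performance — but not
volume conduction, channel covariance of real scalp recordings, EMG/EOG
beyond blinks, or non-stationary spectra. Passing tests therefore
demonstrate that the machinery is correct and that planted effects are
recovered; they do not certify accuracy levels on real EEG.

## Problem sizes and numerical choices

The package's own test suite runs at a desk scale chosen to exercise
every code path in minutes: 128 Hz sampling, 3 subjects, 40 trials of
6 s for the emotion search, 400 trials with 30-trial windows for the
attention search, 3-fold CV with fixed top-20 Fisher selection inside
the search, and 10 generator seeds for the planted-recovery check. The
full-scale parameters (512 Hz, 60-s trials, 1316 trials, 94-trial
windows, 10×10-fold CV, nested selection) remain the defaults of the
corresponding constructors and are a flag away.

Other numerics: deterministic symmetric eigensolvers with a fixed filter
sign convention (largest-magnitude coefficient positive); stable sorts
everywhere a tie could reorder results; RASM epsilon guard $10^{-12}$;
fold assignment from a seedable RNG (default seed 20160814); Hjorth,
Hurst and entropy degenerate cases return flagged zeros rather than NaN,
and the battery enforces finiteness on finite input.

## Known limitations

* The exhaustive k = 8 search (3276 configurations × subjects × CV) is
  expensive in plain R; `budget` subsamples configurations at the cost
  of exhaustiveness, with a warning.
* EDF support covers plain continuous 16-bit EDF without annotations.
* The blink detector is a heuristic stand-in for published detectors.
* GCS adds two metrics estimated from *different* cohorts; its
  per-subject decomposition is only meaningful when both tasks were
  recorded from the same participants.
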