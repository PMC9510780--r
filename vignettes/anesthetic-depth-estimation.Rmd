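---
title: "Estimating anesthetic depth from two-channel ECoG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating anesthetic depth from two-channel ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(anesdepth)
```

## The problem

Monitoring depth of anesthesia (DoA) in laboratory mice lacks the
established electrophysiological indices available for humans. The
analysis this package implements asks which features of a two-channel
epidural electrocorticogram (ECoG), recorded over the left and right
barrel cortex during whisker stimulation, are modulated by the
administered isoflurane concentration, and how well a machine-learning
regressor can recover the instantaneous concentration (or the
attenuation of stimulus-evoked responses) from those features alone.

The experimental design is a piecewise-constant anesthesia protocol:
seven segments at 1.5, 2.3, 1.0, 1.5, 1.0, 2.3 and 1.5 % isoflurane.
At full study scale each segment lasts 15 minutes and the first
5 minutes after every concentration switch are discarded as
transient. Animal recordings of this kind are not publicly deposited,
so the package ships a synthetic generator with known ground truth;
every downstream stage is agnostic to where the recording came from.

## The synthetic generator

`generator_config()` + `simulate_recording()` produce two channels of
"ECoG" at 250 Hz driven by a hidden depth variable `d` in [0, 1],
obtained from the administered concentration by a clipped linear map
`d = (c - 0.8) / (2.5 - 0.8)`. Any monotone map would serve; the
linear ramp keeps the relationship between concentration and hidden
depth as simple as the downstream linearity assumptions require.
After a concentration switch, depth approaches its new target as a
first-order exponential (time constant `transition_tau_s`, default
60 s), emulating the transient that motivates the per-segment discard.

The signal model is a sum of four components, chosen so that each
anesthetic modulation the analysis tests for is individually
controllable:

* **Interhemispheric coupling.** Both channels receive a shared
  band-limited (5--40 Hz) Gaussian source with amplitude weight
  `sqrt(rho(d))` plus an independent band-limited source with weight
  `sqrt(1 - rho(d))`, where `rho(d)` ramps linearly from 0.25 to 0.85.
  For the oscillatory component alone, the long-run magnitude-squared
  coherence is `rho(d)^2`, an analytically predictable level; the
  independent 1/f background dilutes it, which is why tests assert
  monotonicity and relative ordering rather than absolute values.
* **1/f background.** Independent per-channel Gaussian noise
  spectrally shaped to a log-log PSD slope of `-aperiodic_exponent`
  (default 2), 30 uV rms — a typical epidural background level.
* **Line noise.** A fixed 5 uV, 50 Hz sinusoid with random phase per
  channel, left for the notch filter to remove.
* **Evoked responses.** A damped half-sine kernel (25 ms latency,
  40 ms width, 150 uV peak at depth 0) at each stimulus onset of a
  1 Hz train with 2 s on / 2 s off periods; the peak scales by
  `1 - 0.8 d`, so deeper anesthesia attenuates the response. The
  ipsilateral channel receives 30 % of the kernel.

Burst suppression is an alternating-exponential (semi-Markov) gate:
bursts last on average 4 s, suppression episodes `2.5 d` seconds, so
the expected suppression fraction at depth `d` is
`2.5 d / (4 + 2.5 d)` — about 0.07 at 1.0 % and 0.35 at 2.3 %
isoflurane, in the range reported for isoflurane-anesthetized mice.
During suppression all non-line components are scaled to 5 % of their
amplitude. The gate is shared between hemispheres, as cortical burst
suppression is.

What the generator does **not** emulate: biophysical neural-mass
dynamics, pharmacokinetics of isoflurane uptake, electrode artifacts,
non-stationary background drift, inter-animal heterogeneity of the
depth response (all synthetic animals share one concentration-to-depth
map). Tests that pass on this cohort therefore demonstrate that the
pipeline recovers the modulations it assumes, with correctly wired
statistics and no information leakage — not that real mouse ECoG is
this easy. In particular the near-ceiling cross-validated performance
on synthetic cohorts reflects the absence of inter-animal variability,
the dominant error source in the real problem.

## Preprocessing

Both channels pass through a zero-phase (forward--backward) 50 Hz
notch (biquad, Q = 30) and a zero-phase first-order Butterworth
high-pass at 0.1 Hz. Zero-phase filtering uses odd-reflection padding
with step-steady-state initial conditions; the high-pass pads
`3 / cutoff` seconds because its transient decays with a ~1.6 s time
constant. Steady-state rejection at 50 Hz is essentially complete;
a residual transient within a few tenths of a second of the record
edges is inherent to zero-phase IIR filtering and irrelevant here
because the first minutes of every segment are discarded anyway.
Both filters are zero-phase, so their order of application is
immaterial; the notch is applied first, for reproducibility.

Each protocol segment becomes one analysis block after dropping the
first `discard_minutes`; blocks are cut into consecutive
non-overlapping 10 s windows and any trailing remainder is dropped so
all windows are identically sized. Windows never span block
boundaries.

## Features

Per window and channel: Welch PSD (2 s Hann segments, 50 % overlap —
a 0.5 Hz grid and nine segments per window), from which come the
spectral edge frequency (SEF95), the aperiodic log-log slope fit over
20--40 Hz, and band powers (delta 0.1--4, theta 4--8, alpha 8--13,
beta 13--30, gamma 30--45 Hz; the open-ended gamma band is capped at
45 Hz to stay clear of the 50 Hz notch and the 125 Hz Nyquist).
Nine Welch segments keep the coherence estimator's bias floor (~1/9
for independent signals) acceptable; coherence is the
magnitude-squared cross-spectrum averaged arithmetically over 5--40 Hz
bins, with no Fisher-z transform.

Sample entropy is computed over templates spanning 80 ms (20 samples
at 250 Hz): embedding dimension m = 2 with lag 10 so the m-point
template covers the 80 ms span, Chebyshev distance, tolerance
r = 0.2 x window SD, self-matches excluded. Only the 80 ms span is
fixed by the study design; the rest is standard SampEn practice and
config-exposed. Lempel-Ziv complexity binarizes each window against
the **block** median (so all windows of a block share one reference),
parses with the LZ76 exhaustive-history scheme (terminal incomplete
word counted as one), and normalizes the word count C as
`C log2(n) / n`, making values window-length invariant and ~1 for
fair-coin noise.

Burst suppression is detected per block with a 50 ms moving-RMS
envelope thresholded at 0.2 x the block's 90th-percentile envelope;
off-runs shorter than 100 ms are merged back into bursts. No standard
algorithm is prescribed for mouse epidural recordings; this detector
was chosen for determinism and testability against the generator's
known gate. The block-level suppression ratio and mean on/off
durations are replicated onto each window of the block, matching the
row structure the lagged dataset needs. Undefined features (zero
total power, no entropy template matches) are recorded as `NA`,
never silently zero.

Coherence is computed on preprocessed traces by default; a
`coherence_on_raw` flag reproduces the raw-trace variant, since
line-noise removal barely touches the 5--40 Hz average either way.

## Evoked responses and ERA

Trials are `[-0.2, +0.5]` s epochs of the contralateral channel
around each stimulus onset, baseline-corrected by the pre-stimulus
mean; the per-trial amplitude is the maximum absolute post-stimulus
deflection (polarity handling is not prescribed anywhere, and the
absolute deflection is robust to kernel sign). The
evoked-response-attenuation (ERA) target is a trailing moving average
(10 stimuli — length config-exposed) of these amplitudes divided by
the mean amplitude over all stimuli delivered during 1.0 % blocks.
Stimuli inside the discarded transition minutes contribute neither
trials nor the reference, consistent with the block exclusion. ERA is
resampled onto the 10 s window grid by taking the latest value
available at each window's end. Because the trailing average crosses
block boundaries, the first ~10 stimuli after a concentration switch
carry pre-switch amplitudes — visible as a brief lag in the ERA
trace, exactly as a causal monitor would show.

## Modulation statistics

Features are averaged per animal and concentration (pooling repeated
segments), then each unordered concentration pair is tested with a
two-sided Mann-Whitney U test: exact p-values (combined n <= 12,
no ties) or the tie-corrected normal approximation. The
Benjamini-Hochberg step-up controls the FDR. The family structure of
the original "three FDR controls" is ambiguous; the default here is
one family of three pairwise tests per feature, with a
`family = "per_pair"` switch (one control per concentration pair
across features), and the choice is recorded in the report's
attributes. Reports include per-concentration medians and the median
within-segment SD relative to the segment mean.

## The estimator

Inputs stack the feature vectors of the three most recent 10 s
windows (`_t-2`, `_t-1`, `_t-0`); rows never span a block boundary or
discard gap, so no input mixes concentrations across a switch. The
regressor is stagewise least-squares gradient boosting of
depth-capped (<= 3) regression trees, 100 steps, learning rate 0.1
(not prescribed by the study; the standard default, config-exposed),
squared-error loss. It is backed by xgboost configured to plain
stagewise residual fitting (exact greedy splits, `lambda = 0`,
`gamma = 0`, no subsampling, single-threaded — hence bit-deterministic);
tests verify the contract against a ~20-line reference stagewise
rpart booster. Feature importances are total split gains summed over
all trees and normalized to 1 (Gini gain), read from the model dump.

Evaluation is leave-one-animal-out: every animal is the held-out set
exactly once, and no cross-animal normalization exists that could
leak (features are absolute). Fold metrics: MAE, and R^2 against the
**evaluation-set** mean — the conventional choice, noted explicitly
because fold R^2 can then be negative. For the isoflurane target,
predictions are additionally quantized to the nearest of
{1.0, 1.5, 2.3} (exact midpoints go to the lower level — a
probability-zero event on continuous predictions, fixed for
determinism) and one-vs-all macro accuracy, precision, recall and F1
are reported. The ERA target uses the same lag-3 input structure
(the dataset construction is target-agnostic). Prediction traces
carry a trailing "standard error of the past minute" band (6
windows), a purely cosmetic smoothing.

The elapsed-time control fits an identical regressor per fold with
elapsed time as the target and Spearman-correlates its per-fold R^2
with the depth-target R^2: estimators that merely learn elapsed time
would correlate strongly.

A within-animal target permutation (`permute_targets_within_animal()`)
provides the null baseline: it preserves each animal's target
distribution while destroying the feature-target association, and
drives held-out R^2 to or below zero.

## Problem sizes and numerical choices

The analysis scripts and the acceptance checks run a desk-scale
version of the study: 5 synthetic animals, 3-minute segments, with
the 5-minute discard and 60 s transition constant scaled by the same
3/15 factor (1 minute, 12 s) so the block geometry stays
proportional — 12 windows per block, 420 windows per cohort. Setting
`SEGMENT_MINUTES <- 15` in `analysis/00_config.R` restores the
full-scale geometry. Per-animal generator seeds are derived as
`seed + 1000 (i - 1)`, keeping animals independent and cohorts
reproducible.

Edge conditions are handled explicitly rather than silently: a
constant window has sample entropy 0 (every template matches); no
(m+1)-point matches make it `NA`; a single-segment coherence estimate
(identically 1) is rejected; an all-zero block is classified as one
suppression interval; a zero-variance evaluation target makes fold
R^2 `NA`; xgboost treats `NA` features as missing values natively.

## Known limitations

Synthetic animals are exchangeable — the hardest property of the real
problem (inter-animal variability) is absent, so cross-validated
metrics here are upper bounds, not forecasts. The burst detector's
fixed percentile threshold assumes bursts occupy a nontrivial
fraction of every block; recordings that are entirely isoelectric
would need an absolute threshold. EDF input is not supported (no
reader available in the dependency set); recordings travel as CSV
with a JSON sidecar, and the loader refuses data not flagged as
input-referred microvolts. Bispectral coherence, wavelet features
and cross-frequency coupling are out of scope.
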