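---
title: "Modelling glimpsed and masked speech encoding with banded ridge TRFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glimpsed and masked speech encoding with banded ridge TRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glimpsetrf)
```

## The scientific problem

When two people speak at once, each talker's speech arrives at the ear
partly *glimpsed* — spectrotemporal regions where that talker's energy
stands clear of the competing talker — and partly *masked*, where the
competitor dominates. A listener attending to one talker nonetheless
perceives that talker's speech as continuous, which implies that auditory
cortex does something beyond passively registering the acoustic mixture:
masked portions must be restored or inferred. `glimpsetrf` implements an
analysis pipeline for testing how glimpsed and masked acoustic and phonetic
information is encoded in intracranial high-gamma recordings during
two-talker listening, together with a synthetic data generator that makes
every stage of the pipeline testable by parameter recovery.

## The encoding model

The core model is a mass-univariate lagged linear regression — a temporal
response function (TRF). For electrode $e$ with z-scored high-gamma
envelope $y_e(t)$ sampled at 100 Hz, and stimulus feature groups
$g = 1, \dots, G$ with features $x_{g,f}(t)$,

$$ y_e(t) = \sum_{g,f} \sum_{\ell = 0}^{L} w_{g,f,\ell,e}\,
   x_{g,f}(t - \ell) + \varepsilon_e(t), $$

with lags $\ell$ spanning 0–500 ms (51 lags at 100 Hz; −100–600 ms for
display-oriented fits). The weights solve a *banded* ridge problem: each
feature group carries its own penalty $\lambda_g$,

$$ \hat w = \arg\min_w \lVert y - Xw \rVert^2 + w^\top \Lambda w, \qquad
   \Lambda = \mathrm{diag}(\lambda_{g(\mathrm{col})}), $$

so heterogeneous regressors (dense spectrograms, sparse onset impulses,
scaled binary phonetic features) can share one model without one group's
scale dictating the shrinkage of another. `fit_banded_ridge()` solves the
penalized normal equations exactly (Cholesky, with an eigendecomposition
fallback); the equivalent column-rescaling single-SVD formulation is used
inside `tune_lambdas_sequential()`, where reusing a factorization across
penalty scales pays off. Lambdas are shared across electrodes, which keeps
TRF magnitudes comparable between sites.

### Feature construction

* **Spectrograms.** `compute_band_spectrogram()` passes the waveform
  through a log-spaced bandpass filterbank (Butterworth sections,
  forward–backward), takes Hilbert-envelope magnitudes, and averages
  within 10 ms frames. Ten bands over 50 Hz–8 kHz feed the TRFs; a
  100-band version feeds glimpse ratios. Values are linear magnitudes —
  the glimpsed/masked algebra below assumes nonnegativity, and the source
  description of the method leaves compression unspecified, so linear
  magnitude is this package's documented choice.
* **Acoustic edges.** The half-wave rectified temporal derivative per
  band, with frame 0 defined as 0. A talker's edges split exactly into
  `glimpsed = min(edge_talker, edge_mixture)` and
  `masked = max(edge_talker − edge_mixture, 0)`; the two always sum back
  to the talker's edges.
* **Glimpse ratios and phonetic features.** For each forced-aligned
  phoneme, the glimpse ratio is the fraction of fine-band
  time–frequency cells within the phoneme where
  $\text{talker} \ge \text{background} \times 10^{\theta/20}$ at glimpse
  SNR threshold $\theta$ dB (magnitude convention; a power convention
  $10^{\theta/10}$ is selectable). The denominator counts all cells of the
  interval by default; restricting it to cells with nonzero talker energy
  is available behind a flag, since the set-cardinality definition is
  ambiguous about zeros (a zero-energy cell counts as glimpsed only when
  the background is also zero, via the ≥ comparison). Glimpsed and masked
  phonetic regressors multiply each phoneme's binary 22-feature vector by
  the glimpse and mask ratio respectively, so their sum reconstructs the
  plain binary phonetic matrix at every threshold. Phoneme-onset impulses
  are scaled by the same ratios. Word onsets are binary impulses at
  word-initial phonemes.
* **Time quantization.** An interval owns frames
  `[round(start × rate), round(end × rate))`, half-open.
* **Nulls.** Acoustic features are locally time-shuffled in 500 ms
  windows; phonetic features get a shuffled phoneme-to-feature mapping
  (consistent per phoneme, multiset of vectors preserved); word-onset
  nulls place one impulse at a random phoneme onset within each word.

### Lambda selection

`tune_lambdas_sequential()` follows a two-stage schedule: the first two
groups (conventionally spectrogram and glimpsed edges) are tuned jointly by
a polar grid search — the penalty *ratio* is an angle, the common *scale* a
radius, so one eigendecomposition per (fold, angle) serves every radius —
and each remaining group is then tuned one at a time on a log grid with all
earlier lambdas frozen. The objective is mean cross-validated Fisher z over
electrodes; ties break toward heavier regularization. Defaults: 17 angles
interior to $(0, \pi/2)$, radii $10^{-2}$–$10^{5}$ in half-decade steps,
25-point log grids. A reference set of eight per-group penalties
established for this paradigm ships as `lambda_defaults()` and can be used
without re-tuning.

### Cross-validation

Folds are contiguous time blocks (interleaved folds would leak information
across lagged copies). Feature columns are z-scored on training frames
before lagging; the response is centred per training fold; test frames
within one lag span of a fold boundary are excluded from scoring. Accuracy
is the Fisher-transformed Pearson correlation per electrode and fold;
undefined correlations (constant prediction or response) are recorded as
missing and excluded from means with a warning.

## Inference

* **Ablation** (`ablation_test()`): refit with one group removed, identical
  lambdas and folds; `delta_z` per electrode quantifies the group's unique
  contribution. The headline p-value is a hierarchical bootstrap of the
  mean improvement; a one-sided paired t across electrodes is reported
  alongside.
* **Shuffled-feature tests** (`shuffled_feature_test()`): ten refits with
  the group's own null; per electrode, a one-sided one-sample t compares
  the baseline accuracy against the shuffled distribution
  (α = 0.05, uncorrected — this is an electrode-selection device, with
  population-level multiplicity handled by the hierarchical bootstrap).
* **Hierarchical bootstrap** (`hierarchical_bootstrap()`): resample
  subjects with replacement, then electrodes within each sampled subject
  with replacement, keeping that subject's own electrode count. One-sided
  p is the fraction of iterates on the null side, floored at
  $1/N_{boot}$ ($N_{boot} = 10^4$ for reported values).
* **TRF power and latency**: power is the squared weight magnitude
  averaged over features and electrodes per lag (sign-invariant, since
  sites respond with either polarity); SEM is over electrodes. Latency is
  the peak of the 2× band-limited upsampled power curve (5 ms resolution;
  mirror extension suppresses FFT edge ringing; ties break earliest; flat
  curves have no latency). Region-level latencies are read from the
  electrode-averaged curve; per-electrode latencies feed
  `latency_comparison()` (unpaired rank-sum over all significant
  electrodes; paired one-sample t plus hierarchical bootstrap on
  electrodes significant for both features).
* **SNR-threshold sweep** (`snr_threshold_sweep()`): rebuild the phonetic
  regressors at each candidate threshold with lambdas frozen (estimated
  once at 0 dB, per the paradigm's convention), record mean CV Fisher z,
  and compare every threshold against the argmax by hierarchical
  bootstrap.
* **Anatomy** (`anatomical_correlation()`): Spearman correlation between an
  anatomical coordinate and per-electrode `delta_z`, significance by
  hierarchical bootstrap of the correlation. Directional hypotheses use the
  one-sided form.

## The synthetic data generator

`simulate_dataset()` builds everything the pipeline consumes with known
ground truth:

* **Talkers.** Pseudo-phoneme sequences (8-symbol alphabet, distinct
  22-bit feature vectors, Gaussian spectral profiles over the fine band
  axis), lognormal segment durations clipped to 50–250 ms, words of 2–6
  phonemes, rendered directly in spectrogram space as profile × smooth
  amplitude modulation × multiplicative noise. Waveform rendering is
  deliberately not the default — generation in spectrogram space makes the
  regressor round trip exact and fast. Talkers are mixed at 0 dB RMS.
* **Responses.** Each encoded feature group contributes a Gaussian lag
  bump at its scenario latency (sd 35 ms, per-electrode latency jitter
  sd 20 ms) times a loading vector over features; responses are the lagged
  convolution plus Gaussian noise scaled so the oracle prediction
  correlation is `r_target` (0.3 by default — realistic for high-gamma).
  A lognormal per-subject gain (sd 0.15) multiplies the signal, creating
  the within-subject dependence hierarchical inference exists to handle.

### Identifiability of the ground truth

Two structural facts make *arbitrary* ground-truth loadings unrecoverable,
by any estimator: with 8 pseudo-phonemes the 22 phonetic-feature columns
have rank at most 8 (one independent pattern per phoneme), and glimpsed +
masked regressors sum to the binary features, so part of a loading placed
on one group can be re-expressed on the other. The generator therefore
draws loadings in each group's four dominant eigendirections of its own
standardized feature covariance — emulating low-dimensional tuning to the
stimulus dimensions that actually occur — and then removes any component
on which the joint design's null or near-null space (eigenvalues below
$10^{-4}$ of the maximum) concentrates more than half its mass on that
group. The resulting truth is group-pure and estimable in principle, which
is what makes "recovered weights correlate with truth" a meaningful test.
This is a deliberate generator design choice: with isotropic loadings the
recovery target is ill-posed regardless of the estimator, so a failure
would reflect the generator, not the pipeline.

### Scenario presets

`make_scenario_presets()` fixes the study conditions:

| preset | subjects × electrodes | duration | encodes |
|---|---|---|---|
| `stg_like` | 7 × 10 | 600 s | target glimpsed phonetics at 190 ms, masked at 285 ms |
| `hg_like` | 4 × 5 | 120 s | mixture spectrogram at 70 ms, glimpsed phonetics at 110 ms (no masked) |
| `null` | 6 subjects contributing 5, 2, 7, 3, 16, 26 electrodes | 30 s | nothing (acoustic bank only) |
| `threshold_recovery` | 4 × 10 | 60 s | ratio-scaled onsets and phonetics at a configurable true threshold θ\* |
| `flat_threshold` | 4 × 10 | 60 s | threshold-free binary phonetic drive |

Only `stg_like`'s size is dictated by the validation design (it mirrors
the reference study's 7 subjects and ~10 min of audio); the other sizes
are the smallest that keep the respective statistical checks
well-powered. The `null` preset's electrode allocation mirrors a realistic
heterogeneous per-subject contribution. `threshold_recovery` includes the
ratio-scaled phoneme-onset groups because onset impulse amplitudes carry
the most identifiable threshold information; its latencies (150/250 ms)
keep TRF support inside a 0–250 ms fitting window.

## Operating points used in the validation suite

Two penalties appear throughout, expressed per unit-variance column
relative to the number of frames $T$:

* **Prediction-oriented fits** (threshold sweeps) use
  $\lambda = 2T$, near the CV-prediction optimum for these scenarios.
* **Weight-oriented fits** (TRF recovery, latency estimation, ablation
  studies) use $\lambda = 10T$. Cross-validated prediction is nearly flat
  between these two points (mean z 0.325 vs 0.319 on the `stg_like`
  scenario) while weight estimates are markedly more reliable under the
  heavier penalty — the familiar trade-off between predicting responses
  and estimating interpretable filters.

Problem sizes in the validation suite: the STG-like recovery runs at the
full preset (60 000 frames × 70 electrodes); null calibration uses 200
response redraws on one 30 s stimulus with lags 0–100 ms; power uses 10
redraws of the 60 s threshold preset with lags 0–300 ms; threshold
recovery uses 20 runs per true threshold (2 stimulus draws × 10 response
redraws, with per-threshold design factorizations shared across redraws —
numerically identical to independent sweeps); bootstrap calibration uses
500 nested-null draws with a subject effect of sd 0.5 against unit noise,
strong enough that the naive electrode-level t test demonstrably inflates.

## Numerical and design notes

* Edge cases: silence maps to all-zero spectrograms; constant silence
  periods make z-scoring an error (not a silent NaN); degenerate pooled
  SDs drop an electrode with a warning; flat power curves have undefined
  latency; grid optima on a boundary warn that the optimum may lie
  outside.
* The high-gamma chain uses 8 Chebyshev-II bandpasses (order 4, 40 dB
  stopband, stopband edges 5 Hz outside each nominal 10 Hz band — with the
  edges *on* the band the passband would be essentially empty), Hilbert
  magnitudes, averaging, and frame-average resampling to 100 Hz. Frame
  averaging (rather than polyphase resampling) keeps envelope frames
  aligned bit-exactly with the stimulus frame axis.
* Speech responsiveness uses pooled-SD Cohen's D with a strict `D > 0.2`
  retention rule.
* Cohen's D, the dB convention ($10^{\theta/20}$ on magnitudes), the
  all-cells glimpse-ratio denominator, contiguous CV folds, and the
  earliest-peak tie-break are all stated choices where the underlying
  method description is silent; each has a switch or is isolated in one
  function.
* All randomness flows from explicit seeds; `child_seed()` fans a
  top-level seed into per-stage seeds so stages can be rerun in isolation.

## What passing tests do and do not show

The synthetic talkers are *not* naturalistic speech: pseudo-phonemes have
fixed spectral profiles (so phoneme identity is unrealistically readable
from the coarse spectrogram), there is no prosody, pitch, coarticulation,
or lexical structure, and noise is Gaussian at the envelope level. Passing
recovery and calibration tests therefore demonstrates that the *pipeline*
is correct — conservation identities hold, the solver is exact, inference
is calibrated under nested dependence, and planted effects of realistic
size are found with the right latencies and thresholds — not that real
cortex behaves like the presets. Conversely, two known conservatisms are
documented rather than hidden: removal-based ablation is slightly biased
against the baseline under the null (the extra group costs a little CV
accuracy), and the hierarchical bootstrap of a Spearman correlation is
conservative at realistic subject counts (empirical type-I error
~0.01–0.03 at nominal 0.05), so anatomical-gradient calibration sits at
the lower edge of its nominal band.
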