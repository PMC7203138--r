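---
title: "Coherence-based spectro-spatial decoding: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-based spectro-spatial decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohdecode)
```

## The model and its assumptions

The decoder reconstructs a per-trial target signal `y(t)` — a finger
position trace, a speech amplitude envelope — from multichannel neural
features `x_j(t)`. Its central assumption is that **each trial is a
realization of one random process**: the statistical relation between
features and target is stable *across* trials of the same condition, while
nothing is assumed stationary *within* a trial. That matters for natural
stimuli (speech, free movement), whose statistics drift over the course of
a trial.

Estimation has two stages.

1. **Per-feature spectral filters.** Auto- and cross-spectra are estimated
   with one window per trial (window length = trial length, Hamming taper,
   zero overlap), averaging periodogram cross-products across trials. Each
   feature then gets the Wiener deconvolution filter
   `H_j(f) = Pxy_j(f) / Pxx_j(f)`. Because `Pxy` is complex, the phase of
   `H_j` encodes the cross-trial *consistent* phase difference between
   feature and target at each frequency; frequencies without a consistent
   phase relation average toward zero and are automatically attenuated. No
   frequency bands or lag ranges are specified by hand, and there are no
   hyper-parameters to tune.
2. **Spatial combination.** The filtered outputs `x_j * h_j` of all
   training trials, concatenated in time, form a design matrix; ordinary
   least squares (with an intercept — band envelopes have non-zero mean)
   yields weights `b_j` and one combined prediction. The weight magnitudes
   index feature importance and can be mapped over the electrode grid.

Condition-specific models are fitted independently (one per finger, one per
word); the estimator refuses to pool trials across conditions unless
forced, since cross-condition trials are not exchangeable realizations.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `broadband` | 0.1–200 | Hz | conditioning band-pass before anything else |
| `notch` / `notch_q` | 60 / 30 | Hz / – | power-line rejection (biquad, zero-phase) |
| `lfc` | 0.5–40 | Hz | low-frequency component band |
| `hfb` | 70–170 | Hz | high-gamma band whose envelope is extracted |
| `envelope_lp` | 40 | Hz | smoothing of the high-gamma envelope |
| `analysis_fs` | 200 | Hz | analysis rate for features and targets |
| `order` | 4 | – | Butterworth design order (forward–backward) |
| `eps_rel` | 1e-8 | – | relative Tikhonov floor in the spectral division |
| `alpha`, `n_surrogates` | 0.05, 1000 | – | surrogate-test level and resolution |

The high-gamma upper edge is a field convention that varies between 170 and
200 Hz across studies; 170 Hz is the default here and the band is fully
configurable. `eps_rel` exists because `Pxx` can be vanishingly small in
stop-bands after preprocessing; a floor relative to the per-feature
spectral maximum is the smallest intervention that keeps `H` bounded, and
bins with exactly zero power map to `H = 0`.

## Estimator conventions and numerical choices

**Spectral conventions.** Spectra are one-sided densities (per Hz,
window-power normalized), so `Pxx` integrates to signal power; all
normalization constants cancel in both the coherence and the filter. The
cross-spectrum is `E[conj(X) Y]`, which makes `H = Pxy/Pxx` the *forward*
filter: for a target that is a circularly delayed copy of a feature, `H`
comes out as `exp(-i 2 pi f d)` exactly (tested with a rectangular taper,
where the identity is exact). Trials are constant-detrended before
tapering, the default in standard cross-spectral estimators; without it,
trial-to-trial variation in mean level leaks through the Hamming sidelobes
and produces spurious near-DC coherence that can mask genuine low-frequency
peaks. DC and Nyquist bins are forced real in the Hermitian extension so
impulse responses are real to machine precision.

**Prediction** is circular convolution (frequency-domain product with the
full Hermitian `H`), matching the DFT framing of the estimator, with no
taper at prediction time. The filters are non-causal by construction;
causal projection for streaming use is deliberately out of scope.

**Filtering.** "Zero-phase 4th-order Butterworth" is implemented as
forward–backward application of a 4th-order design, giving an 8th-order
magnitude response — the standard reading of zero-phase filtering. All IIR
filters are applied as cascades of second-order sections with the
Butterworth Q factors: at 0.1 Hz on kilohertz-rate data the polynomial
transfer-function form is numerically unreliable (this is also why the
broadband filter runs as a high-pass/low-pass cascade rather than one
8-pole band-pass). Each trial is extended by full-length odd-symmetric
reflection before filtering to tame edge transients. One caveat is
physical, not numerical: a 0.1 Hz high-pass has a settling time longer than
a typical 2–4 s trial, so some sub-band drift survives in any
implementation (the same behaviour is observed with reference
implementations of zero-phase second-order-section filtering); the
downstream band features and the constant detrend in the spectral estimator
make the decoder insensitive to it.

**Resampling** to the analysis rate uses zero-phase anti-alias filtering
(cut-off at 80% of the target Nyquist) plus decimation for integer rate
ratios, and Fourier-domain resampling otherwise; output length is always
`round(n * fs_out / fs)`.

**Degenerate inputs.** Zero-power bins are flagged and set to zero in the
coherence; a rank-deficient spatial design falls back to the minimum-norm
solution with a warning; all-equal weights normalize to 0.5 by convention;
K-means ranking assigns score 0 to features with (numerically) constant
weights instead of failing.

## What is identifiable — and what is not

Two structural properties of the two-stage estimator deserve emphasis,
because they set the limits of what synthetic benchmarks can show.

**Cross-feature leakage.** `H_j` is a *marginal* filter: it regresses the
target on feature `j` alone, per frequency. When several independent
sources contribute to `y`, the finite-trial estimate of `H_j` absorbs a
share of the other features' contributions with relative error of order
`sqrt((F-1)/K)` per frequency bin (`F` features, `K` training trials). The
spatial regression removes the frequency-flat part of this leakage but not
its frequency dependence, so even noiseless, perfectly realizable
feature-level systems are recovered exactly only in the limit `K >> F`.
The realizable-system tests therefore run at small `F` or large `K`; at
the study-scale geometry (8 features, 24 training trials) the same tests
document the expected gap. This is a property of the per-electrode filter
design itself, not of this implementation. Pure-noise features, by
contrast, are nearly harmless: their filters shrink toward zero, and the
regression guard test confirms held-out accuracy is essentially unchanged
when the feature set is doubled with noise channels.

**Scale and split ambiguity.** The product `b_j H_j` is identified, but the
split between filter gain and spatial weight is not. The per-feature
importance used for spatial maps and discriminability analysis is therefore
the *contribution RMS* `|b_j| * RMS(x_j * h_j)` by default, which is
invariant to that split (raw `|b_j|` is available as an option, and the
min-max display normalization follows the raw-weight convention).
Relatedly, when many channels are noisy copies of one common target — the
realistic recording situation — their filtered outputs are nearly
collinear and the *division* of weight among them is determined by their
noise, not by their coupling strengths; only the combined prediction is
stable. Weight-direction recovery is therefore benchmarked on the
feature-level generative model, where independent sources make the split
identifiable, while decoding accuracy is benchmarked on the raw-level
recordings.

## The surrogate significance test

The null hypothesis is "no consistent phase relation at this frequency".
Surrogates replace the target's per-trial Fourier phases with i.i.d.
uniform phases (DC and Nyquist keep magnitude with a random sign),
preserving each trial's amplitude spectrum and Hermitian symmetry, and the
squared coherence is recomputed per surrogate; the per-bin threshold is the
empirical `1 - alpha` order statistic. Only the cross-spectrum changes
under phase randomization, which is what makes 500–1000 surrogates cheap.
Calibration is verified on uncoupled white-noise data: the fraction of
bins where the observed coherence exceeds its threshold must sit inside a
99% binomial band around `alpha` (the acceptance script recomputes this
rate). With very few trials the sign-only null at the DC and Nyquist bins
can saturate, so exceedance claims are made for interior bins.

## Discriminability of spatial patterns

To ask whether conditions differ in *where* information sits, one weight
vector is collected per condition and fold, features are ranked by the
between/total sum-of-squares separation of a K-means clustering of each
feature's weights (k = number of conditions, fixed seed, 10 restarts; ties
broken by feature index), and an LDA classifier on the top-ranked features
(selected on training folds only) is scored on held-out folds by accuracy
and Cohen's kappa.

One design decision here departs from the obvious protocol. If each fold's
weight observation comes from a model trained on the *other* k−1 blocks
(the models of ordinary cross-validation), observations of the same
condition share most of their training trials; their estimation noise is
then correlated within condition, and the LDA separates conditions well
above chance even when the planted spatial patterns are identical — the
analysis would certify structure that is not there. The default scheme
(`scheme = "blocks"`) instead trains each observation's model on its own
disjoint block, making observations exchangeable across conditions under
the null; the null calibration test (and the acceptance script) verify
chance-level accuracy on uncoupled data under this scheme. The overlapping
scheme remains available as `scheme = "cv"` for comparability, with this
caveat documented.

## The mTRF baseline

The comparison baseline expands features with lagged copies over ±500 ms
(step = one sample at the analysis rate, zero-padded at trial edges so
nothing leaks across trials) and fits ridge regression, with the penalty
chosen by nested blocked cross-validation (inner k = 4, the training
block's natural count) maximizing mean per-trial held-out correlation. The
penalty grid is geometric, `1e-6 * 1.848^n` for `n = 0..53`, reaching about
`1.4e8`: a *linear* progression with the same constants would top out near
`1e-4` and cannot span the intended six-to-eight decade range, so the
geometric reading is the default and the linear one is kept behind a flag
for auditability. Ridge solutions are computed on centered data with the
intercept excluded from the penalty; the grid search reuses one SVD of the
design per inner training set.

## What the synthetic generators emulate — and what they do not

`simulate_feature_level()` inverts the decoder's own generative equation:
white-noise features, random smooth unit-norm FIR kernels (25 taps at
200 Hz), random weights, additive white noise scaled so the realized SNR
matches the request exactly. It is the benchmark for *identifiable*
parameter recovery.

`simulate_raw_level()` emulates the structure of a repetitive
finger-flexion experiment at the recording level: pink (1/f) background
noise, a quasi-periodic flexion trace whose cycle periods jitter i.i.d.
with 10% coefficient of variation (free-paced movement), additive
low-frequency coupling through smooth channel kernels, and a 70–170 Hz
carrier amplitude-modulated by the flexion trace — so the LFC *and* the
HFBE of coupled channels both cohere with the target at the flexion rate,
and both peaks must land within one frequency bin of the designed rate.
Coupling gains are calibrated to the requested in-band SNR (10 dB by
default, 6 of 8 channels coupled, 30 trials of 2 s at 1000 Hz — the scale
of a single-condition motor experiment).

`simulate_condition_set()` plants condition-specific weight vectors
(adjacent condition centers `separation` apart on designated features,
shared kernels elsewhere) for end-to-end tests of the ranking/LDA pipeline,
with `separation = 0` as the exchangeable null.

None of the generators model volume conduction, shared artifacts,
electrode-specific noise spectra, non-linear neurovascular-style couplings,
or the anatomical clustering of informative electrodes. Passing tests on
these generators therefore demonstrates correctness of the estimators and
calibration of the inference under the model's own assumptions — not
performance on patient recordings, where noise is structured and coupling
is weaker and less linear.

## Problem sizes and runtime

Test and acceptance computations use the single-condition scale of the
emulated experiments (30 trials, 5-fold blocked CV giving 24/6 splits,
8 channels, 2 s trials; 10 generator seeds for the end-to-end sweep, 20
for null calibrations, 500 surrogates at alpha = 0.05), which keeps the
full suite around a minute on one core while leaving every estimate
comfortably inside its tolerance. Sizes were chosen once from the study
conditions being emulated, and the realizable-system checks use the
`K >> F` geometry that their property actually requires (see the
identifiability section above).

## Known limitations

- Per-electrode marginal filters, not a joint multichannel Wiener solve:
  cross-feature leakage decays only as `(F-1)/K` (see above).
- Circular convolution assumes the trial window is the natural frame; very
  long kernels relative to the trial wrap around.
- The method is designed for discrete trials; continuous streaming use
  would require causal projection of the filters, which is out of scope.
- The surrogate test randomizes target phases only; it tests phase
  consistency between target and features, not all conceivable couplings.
- With `k` folds of very few trials each, the disjoint-block weight
  observations are noisy; planted structure must be strong relative to
  that noise to be detected (the planted-separation tests quantify this).
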