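---
title: "Measuring dimensionality and basis-pattern similarity of population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dimensionality and basis-pattern similarity of population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(popdim)
```

## The model

Trial-averaged population activity is arranged as a matrix whose rows are
time bins and whose columns are neurons (for stimuli: frames by
block-averaged pixels).  After subtracting each column's mean — once,
globally — the activity is modelled as a weighted sum of a small number of
orthonormal *basis patterns*: unit vectors in the feature space, each
weighted by a time-varying latent variable.  PCA supplies the patterns, and
the **dimensionality** is defined as the smallest number of leading
patterns whose cumulative explained-variance fraction reaches a threshold
(0.9 by default, inclusive at equality).  The threshold is a convention,
not an estimate: all conclusions the package supports are *relative*
comparisons of dimensionality at fixed thresholds, never absolute
statements.

## The pattern aggregation statistic

To compare the subspaces occupied under two or more conditions we use the
pattern aggregation method.  Each condition contributes its basis patterns
(`k_A` columns from condition A, `k_B` from B, ...); all columns are
concatenated into one matrix `V` and the **aggregated dimensionality**
`k_agg` is the number of singular values of `V` strictly above a *rank
threshold* `t` (an absolute floor of `1e-10` times the leading singular
value removes exact duplicates even at `t = 0`).  `k_agg` always lies in
the bracket `[max(k_A, k_B), k_A + k_B]`, reaching the lower end when the
subspaces coincide and the upper end when they are orthogonal.

The rank threshold decides how different two patterns must be to count as
separate dimensions.  For two unit vectors at angle `theta`, the singular
values of `V` are `sqrt(1 ± cos theta)`, so the one-to-two transition
happens at `cos theta = 1 - t^2`: `t = 0` splits on any deviation, `t = 1`
demands orthogonality, and the default `t = 0.5` places the transition near
41 degrees — a compromise we keep throughout.

Because randomly drawn subspaces are *not* halfway between the extremes
(in a high-dimensional ambient space they are nearly orthogonal), the
observed `k_agg` is compared to a Monte-Carlo **chance level**: repeatedly
draw independent orthonormal sets of the same sizes uniformly in the
ambient space (orthonormalized standard-Gaussian matrices, which is
rotation invariant) and aggregate them.  A constrained null — drawing from
an `M < N` dimensional space when circuit constraints limit the patterns a
population can express — is the same computation at ambient dimension `M`.
Two summaries follow:

* the **similarity index** `s = (mean chance - k_agg) / (sum k - max k)`,
  positive when patterns overlap more than chance, negative when they are
  closer to orthogonal than chance, and in `[-1, 1]` whenever the chance
  mean lies inside the bracket;
* a **permutation probability**: the add-one tail estimate
  `p = (1 + #{chance draws <= k_agg}) / (1 + n_draws)` (or the mirrored
  tail), never exactly zero.  What is "permuted" under this null is the
  orientation of each condition's subspace; with `1e5` draws an observed
  value below every draw reports `p < 1e-4`.

For more than two sets the same normalization is used with the max over
all sets; this multi-set extension is an assumption of this package (only
the two-set formula has a published form).

```{r}
a <- random_orthonormal(100, 5)
x1 <- center_features(data_matrix(matrix(rnorm(200 * 5), 200, 5) %*% t(a)))
x2 <- center_features(data_matrix(matrix(rnorm(200 * 5), 200, 5) %*% t(a)))
pattern_similarity(list(x1, x2), n_draws = 200, rng_seed = 2)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `variance_threshold` | 0.9 | cumulative variance fraction defining `k`; 0.7/0.8 give the same relative orderings |
| `t` (rank threshold) | 0.5 | singular-value cutoff for aggregated patterns; two-vector transition at `arccos(1 - t^2)` |
| `n_draws` | 1000 | chance draws (use `1e5` for tail probabilities; 100 reproduces typical error bars) |
| `bin_width` | 20 ms | PSTH binning; rates are counts / bin seconds, a pure rescaling PCA ignores |
| window length | 1 s (50 bins) | time-resolved analyses; windows tile the record without overlap |
| subsample fraction | 0.5 | error bars: dimensionality of 100 half subsamples, sd reported |

Centering deserves emphasis: features are centered exactly once, globally,
and every windowed analysis consumes row slices of that globally centered
matrix.  Window-local means are never re-subtracted, so all windows share
one reference frame and their dimensionalities are comparable.  The
`rate_filter()` convention is strict: a neuron is kept only if its mean
rate *exceeds* 1 spike/s.

## Stimulus generators

The package regenerates its three stimulus classes procedurally, at the
geometry used throughout: 80 pixels per degree, 25 Hz effective frame
rate, 750 frames per 30-s movie, and a fixed preprocessing pipeline
(center-crop to 320 x 320, average fixed 8 x 8 blocks, flatten to a
1600-vector per frame, centre).

* **Gratings movie** — 98 equally spaced drift directions (3.67 degrees
  apart) at 1.3 cycles/degree and 6.25 Hz, 300 ms per element plus two
  blank elements, inside a 640-px circular aperture.  300 ms at 25 Hz is
  7.5 frames, so elements alternate 8 and 7 frames to total exactly 750;
  each element starts at phase 0 (the within-element phase set
  {0, 1/4, 1/2, 3/4} cycle is the same for any starting phase, so this
  convention is immaterial to PCA).  The central 320-px crop lies fully
  inside the aperture, so cropped frames show no aperture edge.
* **Noise movie** — 750 frames of a 40 x 40 grid of 8 x 8-px squares with
  independent uniform intensities, the grid jittered 1-8 px per frame and
  axis (fresh squares enter at the edges).  Jitter misaligns square
  borders with the fixed preprocessing blocks, which is what leaves the
  residual spatial correlation visible in its eigenspectrum.
* **Natural-movie surrogate** — a stand-in for a real film with three of
  its statistical signatures: a 1/f^2 spatial power spectrum, AR(1)
  frame-to-frame correlation of the Fourier field (0.8 by default), and a
  slow global-luminance drift.  The drift amplitude default (0.2) was set
  so the surrogate reproduces two qualitative signatures of real film
  footage: the leading pixel pattern is the global-luminance (all-same-
  sign) direction, and the whole-movie dimensionality at 90% lands in the
  60s, between the gratings and noise movies.  The surrogate deliberately
  contains *no* higher-order structure — no edges, objects, or occlusions —
  so analyses that depend on losing such structure (notably phase
  randomization) act on it only through temporal decorrelation; passing
  tests on the surrogate demonstrate the machinery, not the full
  phenomenology of natural movies.

The parametric manipulations operate per frame: contrast scaling about
each frame's own mean; phase randomization with offsets uniform on
`[-alpha, alpha]` applied antisymmetrically over conjugate frequency pairs
(DC untouched, so mean luminance is conserved and the output is exactly
real); and spectral flattening, which normalizes the power spectrum by its
sum, raises it to an exponent `q`, and rescales — turning a 1/f^2 spectrum
into 1/f^(2q) while preserving phases.

## The receptive-field model

One hundred (by default) model V1 neurons are simulated in four stages:
(1) a space-time Gabor filter — Gaussian envelope times sinusoid on
coordinates rotated by orientation and drift direction, unit Frobenius
norm, integrating the past 15 frames — followed by half rectification;
(2) subtraction of a rectified, weighted untuned drive (difference of 2-d
Gaussians, scales 20 and 30 px, applied to the current frame); (3)
divisive normalization by the mean stage-1 output of all other neurons
plus a positive offset; (4) a pointwise power law `max(0, x)^q`.  Fixed
values: temporal frequency 6.25 Hz, RF centers Gaussian around the frame
center ("variance 20" is taken literally, sd about 4.5 px), envelope base
scale `20 + |N(0, 1)|` px.  Per-neuron parameters without a published
closed form (aspect ratio, spatial frequency, suppression weight,
normalization offset, output exponent, direction selectivity) get
plausible, fully overridable lognormal/half-normal/uniform defaults in
`default_rf_config()`; consequently only *trends* of model dimensionality
across stimuli are meaningful, never its absolute values.  A direction
constant `d = 0` makes the temporal envelope a single-frame delta (the
`sigma_t -> 0` limit), and the first 14 frames, which lack a full filter
history, are dropped rather than zero-padded so no artificial onset
dimension enters the analyses.

## Fractal (correlation) dimensionality

As a nonlinear cross-check, `neighbor_curve()` counts, for 50
logarithmically spaced radii between the 1st and 99th percentiles of
pairwise distances, the mean number of other points within radius `r` of
each point; the slope of log count versus log radius, fitted by ordinary
least squares inside bounds on the *log-count* axis, is the correlation
dimensionality.  Natural logs are used (slopes are base invariant).  The
shipped defaults for the fit bounds, `(6, 12)`, suit clouds the size of
the full movie analyses; for the `1e4`-point validation clouds the tests
fit inside log counts `(2, 6)` — roughly 7 to 400 neighbors per point —
which keeps the fit in the scaling region, below the radii where boundary
effects and saturation flatten the curve.  On such clouds the estimator
recovers 1 on a line segment and 2 on a filled square within a few
percent, and underestimates a planted 5-dimensional Gaussian cloud by
about 10%, the usual behaviour of correlation-dimension estimates at
finite sample size.

## Numerical choices

* Singular values below `1e-12` of the largest are treated as exact zeros
  when forming variance fractions; the cumulative rule is inclusive
  (`>=` threshold) with a `1e-12` guard for accumulated rounding.
* Pattern signs are fixed (largest-magnitude coefficient positive) so
  serialized pattern sets are reproducible; aggregation is invariant to
  column signs and order.
* `effective_rank()` demands unit-norm columns to `1e-8` and uses strict
  `sigma > max(t, 1e-10 sigma_1)`.
* Gaussian smoothing of time-resolved curves (sd 1.5 s) truncates and
  renormalizes the kernel at the record edges, so constant curves pass
  through unchanged.
* Degenerate inputs fail loudly: zero-variance matrices, all-identical
  point clouds, a single pattern set in the similarity index, windows
  longer than the record.  Zero-variance windows in the similarity matrix
  are flagged missing and excluded from the off-diagonal mean.

## Problem sizes used by the shipped tests

The test suite regenerates all fixtures in code.  The stimulus
reproductions run at full published scale (750-frame movies, 1600-pixel
feature space).  The receptive-field trend suite runs 5 seeds at a reduced
scale chosen once — 50 neurons, 200-frame 64-px surrogates, keeping the
samples-per-neuron ratio near that of the full-scale analyses — and checks
the direction of the Spearman correlation between manipulation level and
stage-4 dimensionality.  Synthetic-recovery tests plant known subspaces in
a 100-neuron space and verify the similarity index returns near 1 (shared)
and near 0 (orthogonal).

## Known limitations

* The surrogate's lack of higher-order structure means the
  phase-randomization analysis cannot exhibit the structure-loss effect it
  probes on real films (see above); on the surrogate the stage-1..3
  dimensionality *rises* with the randomization range because frames
  decorrelate in time, while stage 4 usually, but not always, falls.
* The stage-4 power law collapses dimensionality to a handful of
  dimensions, so stage-4 trends are noisy at desk scale; stage-3 trends
  are much cleaner.
* The gratings-movie generator follows the printed stimulus parameters
  exactly; its pixel dimensionality at 90% is 30, which is sensitive to
  the number of grating cycles across the analysis crop (about 5.2 here).
  Geometry variations within plausible display conventions move this
  value by several dimensions, so comparisons against other pipelines
  should fix the geometry first.
* Chance draws treat each condition's subspace as uniformly random and
  independent; if the recorded population can only express an
  `M`-dimensional repertoire, use the constrained null.
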