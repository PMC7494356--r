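---
title: "Local texture statistics, maximum-entropy synthesis, and efficient-coding threshold prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local texture statistics, maximum-entropy synthesis, and efficient-coding threshold prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliderstats)
```

# The model

`gliderstats` implements a complete workflow for studying local multi-gray-level
image textures: a translation-invariant coordinate system for the statistics of
2x2 pixel blocks, algorithms to synthesize textures with prescribed
coordinates, a preprocessing pipeline that maps photographic image ensembles
into this coordinate space, and the "variance is salience" efficient-coding
prediction that links the natural variability of each coordinate to human
detection thresholds, together with the psychometric and evaluation machinery
needed to test that prediction.

## The texture coordinate system

A texture is modeled by the joint distribution of gray levels in a 2x2 block
("glider") of checks, each level an integer in `0..G-1` (G = 3 by default:
black, gray, white). The `G^4` block probabilities over-parameterize a
stationary texture; a non-redundant system is obtained through the discrete
Fourier transform over the group `Z_G^4`. Every character of that group is
indexed by a coefficient vector `s = (s1, s2, s3, s4)` over the glider
positions (row-major: `A1` top-left, `A2` top-right, `A3` bottom-left, `A4`
bottom-right), and the corresponding statistic is the distribution of

    h = s1*A1 + s2*A2 + s3*A3 + s4*A4 (mod G).

Two reductions make the system minimal:

* **Translation.** Stationarity makes a coefficient pattern equivalent to any
  translate of its support; the canonical representative has its support
  touching row 1 and column 1 of the glider.
* **Unit scaling.** Multiplying `s` by a unit `u` modulo `G` only relabels
  `h` to `u*h`; the canonical representative is the lexicographically
  smallest unit multiple, which for prime `G` puts a leading coefficient 1.

Each equivalence class is a *texture group*; its `G` probabilities sum to one,
so it contributes `G - 1` free coordinates. For `G = 3` there are 33 groups —
1 first-order, 8 second-order (four pair orientations, each with a sum and a
difference variant), 16 third-order, and 8 fourth-order — hence a
66-dimensional space; for `G = 2` the same enumeration yields the familiar
10 dimensions. `analyze()` estimates the coordinates of a patch by gliding
the minimal shape containing each group's support and counting modular values
(integer-exact counts; `boundary = "periodic"` wraps around and makes the
counts exactly stationary, which the test oracles exploit).
`coords_from_block_probs()` and `block_probs_from_coords()` convert between
block distributions and coordinates through the character sums; the inverse
transform reports an infeasibility error when a requested coordinate vector
corresponds to no nonnegative block distribution.

Group naming pairs a greek letter per order (γ, β, θ, α) with the row-major
coefficient signs (trailing zeros dropped), e.g. `β++` (horizontal sum),
`β+0-` (vertical difference), `β+00+` (main diagonal sum), `β0+-`
(anti-diagonal difference); since sign strings alone cannot distinguish all
orientations, every group also carries a positional identifier such as
`AC_1_2` (positions A..D = the four glider cells, followed by the nonzero
coefficients) which is the stable key used in files and code.

## Plane geometry and the coordinate embedding

Within one group, the `G` probabilities live on a simplex whose center
(`1/G` everywhere) is the unbiased texture. Each group is embedded into
`R^(G-1)` using unit simplex vertex vectors `v_h` (for `G = 3`, at angles 90,
-30, and 210 degrees): `w = sum_h p_h v_h`. This embedding is the package's
working metric, chosen for three properties: the origin maps to zero, a
vertex (one probability equal to 1, "full saturation") has norm 1 so that
*texture contrast* is plain Euclidean distance, and every direction within a
simple plane (one group varied) or a mixed plane (one probability axis from
each of two groups) is automatically a unit vector. Covariances, predicted
thresholds, and plane angles are all computed in this flattened
66-dimensional embedding (`embed_coords()`, `plane_direction()`,
`plane_point()`, `direction_vector()`).

## Maximum-entropy synthesis

`synthesize_single_group()` generates a patch whose statistic in one group is
an i.i.d. sample from the requested probabilities. Cells are visited in
raster order (implemented as vectorized anti-diagonal wavefronts): cells that
cannot complete a glider placement are seeded i.i.d. uniform, and every later
cell is solved from a fresh draw `h ~ probs` of the constrained statistic.
The construction realizes the maximum-entropy distribution subject to the
constraint, reaches any point of the probability simplex (point masses are
satisfied exactly — every placement, not just on average), and is
deterministic given its seed.

Two caveats are worth stating precisely. First, maximum entropy forces only
statistically *unrelated* groups to their unbiased values: a group whose
coefficient vector is a sum of translates of the constrained one (a
"harmonic") necessarily inherits structure — for a horizontal-sum constraint
with distribution `p`, the four-point statistic `A1+A2+A3+A4` is distributed
as the convolution `p * p`. Second, under a saturated constraint the
placements of other groups are no longer independent across the patch even
though their marginal stays uniform, so distributional comparisons against
i.i.d. ensembles are only valid for vacuous constraints; the tests respect
both caveats.

`synthesize_mixed()` pins one probability axis in each of two groups. The
sequential scheme is kept but the local conditional is the product of the two
groups' weight factors. The product rule is exact when either constraint sits
at its unbiased value and acquires an `O(saturation^2)` bias otherwise, so
the weights are *calibrated*: five probe patches (128x128) are synthesized
and the weights updated multiplicatively until the realized coordinates match
the request. Feasibility is detected constructively, in two ways: a cell with
no admissible gray level (zero conditional mass) aborts immediately, and a
calibrated construction that still deviates by more than 0.05 from the
requested axis probabilities is declared infeasible — such unreachable
combinations genuinely exist once both groups approach saturation.

`make_stimulus()` renders the four-alternative forced-choice arrays used in
texture segregation experiments: a 64x64 check array with a 16-check-thick
strip at an 8-check margin from one side (rows 9-24 for `side = "top"`), one
region structured and the other i.i.d. uniform.

## The image pipeline

`run_pipeline()` composes, in order: elementwise log of luminance (natural
scenes have approximately lognormal intensities; images already log-encoded
skip this), `N x N` block-average downsampling (default `N = 2`, suppressing
sensor-level artifacts), splitting into non-overlapping `R x R` patches
(default `R = 32`), spectral whitening, rank ternarization, texture analysis,
and blur rejection. Partial blocks and patches are dropped, never padded.

* **Whitening** divides each patch's Fourier transform by the square root of
  the ensemble-average power spectrum, removing the average pairwise
  correlations so the analysis focuses on higher-order structure. The filter's
  DC gain is set to zero: the subsequent rank-based ternarization is
  insensitive to the patch mean, and retaining DC would let luminance
  variance dominate the filter. By construction the ensemble-mean spectrum
  after filtering is exactly flat.
* **Ternarization** (`ternarize()`) ranks the pixels within each patch and
  assigns the lowest third to black, the middle third to gray, and the top
  third to white (counts within 1 of `R^2/3`); ties are broken by a seeded
  random permutation, which is deterministic and unbiased across levels.
  This histogram equalization deliberately discards the first-order
  (contrast/brightness) statistics, pinning the first-order coordinates at
  their unbiased values.
* **Sharpness** is measured on each patch's *raw* pixel region before any
  other processing: luminances are normalized by their median, convolved with
  the 3x3 Laplacian cross, and the median absolute interior response is
  returned (scale-invariant, no assumptions about pixels beyond the image
  border).
* **Blur rejection** (`remove_blurred()`) fits a two-component Gaussian
  mixture with unshared full covariances to the embedded texture vectors
  (all 66 coordinates) and keeps the component whose members have the higher
  median sharpness. The EM uses seeded k-means initialization with 10
  restarts and a small relative ridge on the covariances; the ridge matters
  because ternarization leaves the first-order coordinates nearly constant,
  which would otherwise make the component covariances singular.

## Threshold prediction and psychophysics

In the sampling-limited regime of efficient coding, the detection threshold
along a texture direction is predicted to be inversely proportional to the
standard deviation of natural texture statistics along that direction.
`fit_gaussian()` fits a mean and covariance to the embedded vectors of the
retained patches (variance is taken about the sample mean, the standard
meaning of standard deviation), and `predict_threshold()` returns
`(u' S u)^(-eta/2)` for the direction's unit vector `u`. The default
exponent `eta = 1` is the plain reciprocal standard deviation; `eta = 0`
makes all predictions equal (no information from the data), and `fit_eta()`
estimates the exponent by weighted least squares of log measured thresholds
on negative log standard deviations. Predictions carry an arbitrary overall
scale; `fit_scale()` fits the single multiplier minimizing the
uncertainty-weighted squared log error in closed form. Within any plane the
predicted thresholds lie exactly on an origin-centered ellipse (the radius is
`(c' M c)^(-1/2)` for a quadratic form `M`), a property the tests assert via
`fit_threshold_ellipse()`.

Psychometric data are modeled with a base-2 Weibull for four-alternative
forced choice: `fc(c) = 0.25 + 0.75*(1 - 2^(-(c/lambda)^k))`, so chance is
0.25, the guess rate is fixed, the lapse rate is zero, and `lambda` is
*exactly* the threshold criterion of 0.625 — halfway between chance and
ceiling. `fit_threshold()` maximizes the binomial likelihood over
`(log lambda, log k)` and attaches a bootstrap log-space standard error
(trials resampled within contrast, 1000 resamples by default, percentile
68% half-width) plus a 95% interval. Thresholds extrapolating beyond the
tested contrasts are returned as-is and flagged: an extrapolated or unbounded
threshold signals a low-sensitivity direction, not a fit failure.
`align_subjects()` combines observers multiplicatively (per-subject
sensitivity factors, geometric-mean-1 normalized, alternating means on log
thresholds) and reports the variance explained; `combine_errorbars()` pools
log-space error bars by root mean square.

## Symmetries

`symmetry_transformation()` pairs one of the eight square symmetries
(rotations clockwise; the six conventionally named ones plus the two
transpositions that close the group under composition) with an affine
gray-level map `v -> a*v + b (mod G)`. For `G = 3` the affine maps realize
all six permutations of the levels (`gray_exchange()` provides the named
swaps); non-affine permutations for larger `G` are rejected because only
affine maps act linearly on the modular statistics. The induced action on
coordinates is an exact permutation of `(group, h)` entries, derived by
pulling each coefficient vector back through the geometry and re-canonicalizing:
`h` maps to `a*u*h + b*sum(s)`. The package treats
`transform_coordinates()`-vs-patch-level agreement as a hard identity (exact
equality under periodic analysis), and `threshold_change()` computes the
log-threshold differences that a transformation induces on a measured or
predicted threshold set, excluding directions fixed by the transformation and
directions whose image carries no data — both exclusions are reported.

## Evaluation statistics

Agreement between predicted and measured thresholds is summarized by the
median absolute log error (`median_abs_log_error()`; for mismatches of this
size the log error is numerically close to relative error). Significance is
assessed by a permutation test: measured thresholds are shuffled across
direction labels (optionally only within planes, the variant appropriate when
the within-plane ellipse structure should be preserved under the null) and
the statistic recomputed; the p-value `(1 + #{null <= obs}) / (1 + n_perm)`
can never be exactly zero. Defaults use 10,000 permutations.

## Synthetic fixtures

`generate_images()` produces ensembles with the broad statistics the pipeline
is designed around: Gaussian random fields with power-law spatial spectra
(power `~ 1/f^2` by default) exponentiated to lognormal intensities, and a
labeled fraction blurred by a Gaussian kernel (defaults: 24 images of
256x256, 25% blurred with sigma = 3 px, log-sd 0.5). Two heterogeneity
parameters are central to the design: each image draws its spectral exponent
(sd 0.3) and its horizontal anisotropy (median 1.5, log-sd 0.4) around the
ensemble values. The whitening filter removes whatever spectral structure is
*shared* across the ensemble, so a perfectly homogeneous ensemble would leave
almost no variance in texture space; it is scene-to-scene variation — as in
real image collections — that survives whitening and gives the texture
distribution direction-dependent variance. With these defaults the predicted
thresholds across second-order planes span roughly a factor of two, enough
for the end-to-end recovery experiment to be decisively non-trivial.

The fixtures are deliberately minimal: log-Gaussian fields have no edges,
occlusions, or phase structure, and their blur model is a single isotropic
kernel. Passing the end-to-end tests therefore demonstrates that the chain
of estimators is consistent and unbiased — not that any scientific claim
about real scenes holds; analyses of real photographs should feed the
pipeline actual calibrated luminance images.

`generate_observer_data()` simulates the psychophysical design (12 directions
per plane, 3 contrasts per direction spread multiplicatively around the true
threshold, 360 trials per direction, binomial outcomes from the Weibull
observer), recording the ground truth for recovery tests.

# Numerical choices and problem sizes

* Counting statistics are held as integer numerators, so normalization,
  marginalization, and symmetry identities are bit-exact, not approximate.
* The Fourier inversion clips reconstructed block probabilities in
  `[-1e-9, 0)` to zero and errors below that tolerance.
* Mixed-plane calibration: 5 iterations on 128x128 probes, infeasibility
  declared beyond 0.05 residual deviation.
* The blur-rejection EM uses ridge `1e-6` times the mean coordinate variance,
  200 iterations, relative log-likelihood tolerance `1e-8`.
* Weibull fits start from the contrast nearest the 0.625 criterion with
  shapes {1, 2, 4}; bootstrap refits warm-start from the point estimate.
* The test suite exercises the chain at sizes chosen to make sampling error
  small relative to the tolerances while keeping a laptop-scale run: 24
  synthetic images of 256x256 (384 patches), 96 probed directions, 10
  synthesis seeds at size 64 per round-trip target, 200 simulated observers,
  10^5 samples for covariance recovery, and 2000 permutations where the
  resolution `p <= 1/2001` suffices.

# Known limitations

* Mixed-plane synthesis calibrates to the requested axis probabilities within
  sampling error rather than satisfying them exactly per placement, and its
  residual bias grows near saturation; single-group constraints are exact.
* For composite `G` (4, 6, ...), unit-orbit enumeration still works but
  coefficient vectors with non-unit leading entries form their own classes
  and the `sum(G-1)` dimension formula no longer counts free parameters
  correctly; `G = 2` and `G = 3` (and prime `G` generally) are the supported,
  tested cases.
* The Gaussian model of the texture distribution is a second-moment
  summary; directions with strongly non-Gaussian natural statistics may be
  predicted poorly no matter how much data the pipeline sees.
* Subject alignment uses a single multiplicative factor per subject; richer
  hierarchical observer models are out of scope.
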