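---
title: "Histogram texture analysis of cortical bone micro-CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram texture analysis of cortical bone micro-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexture)
```

## The measurement problem

Micro computed tomography of small-animal femora produces 8-bit gray-level
volumes in which voxel intensity is proportional to local x-ray attenuation
and hence, in cortical bone, to local mineral density. Conventional
morphometry condenses a region of interest (ROI) into a single average —
a bone mineral density (BMD) — and discards the shape of the intensity
distribution. Two bones with identical mean intensity can have very
different intensity *distributions*, and distributional features (spread,
asymmetry, uniformity, heterogeneity) plausibly track bone quality and
fracture resistance. `cortexture` quantifies the full first-order
distribution of the ROI.

## The texture parameters

Let $P_k$ be the normalized histogram height at gray level
$k \in \{0, \dots, 255\}$, built from all ROI voxels. The package computes:

| Parameter | Definition | Reading |
|---|---|---|
| mean $\bar m$ | $\sum_k k P_k$ | average local density |
| sigma $\sigma$ | $[\sum_k (k-\bar m)^2 P_k]^{1/2}$ | mineralization peak width |
| skewness | $\sigma^{-3}\sum_k (k-\bar m)^3 P_k$ | asymmetry; negative = long low-density tail |
| kurtosis | $\sigma^{-4}\sum_k (k-\bar m)^4 P_k - 3$ | peakedness relative to a Gaussian |
| energy | $\sum_k P_k^2$ | uniformity; 1 iff one occupied level |
| entropy | $-\sum_k P_k \log P_k$ | heterogeneity; 0 iff one occupied level |
| Nakagami | $\mathrm{E}^2(X^2)/\mathrm{Var}(X^2)$ | concentration of the squared-intensity law |

plus the *below-first-quartile fraction* $\sum_{k \le 64} P_k$, a proxy for
the share of low-density bone voxels.

Numerical conventions, fixed once and documented here:

* **Entropy sign and base.** Entropy is the standard negative sum; the
  default base is the natural logarithm (nats), selectable to base 2. The
  natural base is what makes the analytic worked examples below come out at
  4.63/5.23/5.43 (a unit-bin Gaussian of scale 25 has differential entropy
  $\tfrac12\ln(2\pi e\, 25^2) \approx 4.64$ nats).
* **Summation range.** All 256 levels contribute; the $k = 0$ term matters
  for energy and entropy even though it vanishes in the mean.
* **Population moments.** Sigma and the Nakagami moments divide by $N$, not
  $N-1$: the statistics describe the voxel population of one ROI
  (typically $N \sim 10^5$, where the correction is negligible), and the
  histogram path and pixel path then agree to machine precision — a
  property the test suite asserts at $10^{-9}$.
* **Degenerate input.** A constant ROI has $\sigma = 0$ and
  $\mathrm{Var}(X^2) = 0$; skewness, kurtosis and the Nakagami parameter
  raise classed errors rather than return sentinels, so that group
  summaries can never silently average infinities.

## Region of interest

The ROI is a slab of fixed physical length (default 0.5 mm) along the
long axis at the mid-diaphysis (default center fraction 0.5), converted to
a slice count by round-half-up of `length_mm * 1000 / voxel_size_um` with a
minimum of one slice; at the 9 µm voxel size of the emulated scanner the
default slab is 56 slices. A slab that does not fit the volume is an error;
nothing is clipped silently. Within the slab, voxels with intensity at or
above `mask_threshold` (default 50) count as cortical bone. The threshold
replaces the manual contouring a radiologist would approve on real scans:
it is reproducible, and with the synthetic generator's near-zero
marrow/background and cortical intensities around 100 the default
separates the compartments by a wide margin. Whether marrow voxels inside
the cortical shell should be contoured out or thresholded out on real data
is a user decision; the threshold is this package's stand-in.

## Analytic worked examples

Three closed-form densities on $[0, 255]$ — Gaussians of scale 25 and 50
at location 128, and a Rayleigh of scale 100 — illustrate that one mean
does not determine a distribution. They are discretized by point
evaluation at the integer levels (not bin integration; the simplest
convention, and the one that reproduces the published reference values of
this worked example most closely). Two conventions coexist deliberately:

* entropies use the **renormalized** discretization (the histogram is made
  to sum to one);
* first-quartile percentages use the **un-renormalized** one (truncation
  losses at the range ends are kept).

No single convention reproduces all six reference values simultaneously —
the renormalized entropy of the scale-50 Gaussian computes to ≈ 5.28
against the quoted 5.23, and the un-renormalized Rayleigh quartile mass to
≈ 18.78% against 18.89% — so the package states its convention, and its
tests bound the residual gap (±0.06 nats, ±0.7 percentage points) rather
than guess an unstated code path. The Rayleigh's analytic mean is
$100\sqrt{\pi/2} \approx 125.3$, not 128; the package does not pretend
otherwise.

```{r worked}
wx <- worked_example_table()
wx$table
wx$r_squared
```

The demonstration images (`demo_images()`) contrast a uniform 16×16 image
at level 128 (energy exactly 1, entropy 0) with a shuffled image of the
same mean. The shuffled image draws 128 levels and pairs each draw $k$
with $256-k$ before shuffling, so its pixel **sum** is exactly
$256 \times 128$ and the two images share the mean exactly — a stronger
guarantee than resampling until the mean is close.

## The synthetic cohort generator

No scanner data ships with the package; the generator produces volumes
with the statistical structure the analysis assumes, so every stage is
testable end to end.

* **Intensity law: skew-normal.** The published group summaries report
  mean, sigma and a distinctly negative skewness for both diet arms
  (control: 98.1, 17.8, −0.906; low-magnesium: 105, 12.6, −0.729). The
  skew-normal is the minimal standard family with exactly these three
  degrees of freedom; its attainable skewness $|\gamma_1| < 0.9953$ covers
  both arms. Kurtosis is left emergent (the corresponding published group
  difference was not significant). Moment matching is exact and closed
  form: with $c^3 = 2\gamma_1/(4-\pi)$, the scaled mean parameter is
  $m = c/\sqrt{1+c^2}$, giving shape $\delta = m\sqrt{\pi/2}$, scale
  $\omega = \sigma/\sqrt{1-m^2}$ and location $\xi = \mu - \omega m$. A
  round-trip test verifies the analytic moments of the returned parameters
  at $10^{-6}$.
* **Geometry.** An annular cylinder — cortical shell between canal radius
  and outer radius (defaults 20 and 40 voxels over 56 slices, ≈ 2×10⁵
  shell voxels, the order of a real mid-diaphysis ROI) — with canal and
  background at level 0.
* **Discretization.** Draws are rounded half-to-even (unbiased) and
  clipped to $[0, 255]$; at the default moments the clipped tails are
  ≳ 5σ out, so recovery of the targets is limited only by sampling noise.
* **Independence.** Voxels are independent; the analysis is
  histogram-based and order-blind, so spatial correlation would not change
  any statistic computed here. This is also the generator's main departure
  from real micro-CT, along with the absence of reconstruction physics
  (beam hardening, ring artifacts, partial-volume blending). Passing tests
  therefore validate the *pipeline*, not the biology: they show the
  statistics, ROI logic and inference behave correctly on data whose
  ground truth is known.
* **Determinism.** Every specimen's sub-seed is a fixed arithmetic
  function of the group seed and specimen index; identical inputs give
  identical volumes.
* **Between-specimen variability** is a knob (`specimen_jitter_sd`, a
  per-specimen shift of the target mean) defaulting to 0, because the
  published dispersion column is ambiguous (SD vs SEM) and deriving a
  value from it would be a guess. With the default, specimen-to-specimen
  scatter is pure sampling noise.

The five-insert BMD phantom emulates a hydroxyapatite calibration phantom:
densities 200–1000 mg-HA/cm³ map linearly to gray levels (default
200→60, 1000→220, a choice that keeps all inserts comfortably on the
8-bit scale; no physical attenuation-to-gray mapping is published for the
emulated scanner, so the mapping is a package default, not a calibration).
Gaussian noise of 10 gray levels — a realistic micro-CT noise floor that
keeps the brightest insert more than 3σ below clipping — is added
everywhere and the volume is rounded and clipped. For a noisy-constant
insert at mean $\mu$ and noise $s$ the Nakagami parameter is
$(\mu^2+s^2)^2/(4\mu^2 s^2 + 2s^4)$, an increasing and mildly convex
function of $\mu$: the phantom therefore predicts a strictly increasing,
near-linear Nakagami–density relation, which the tests assert
($r^2 \ge 0.95$) without claiming the published real-phantom value.

## Group comparison

`compare_groups()` mirrors the conventional report: one row per parameter
with per-group mean and SD, a two-sided p-value, and the signed percent
change $100(\bar x_B - \bar x_A)/\bar x_A$ computed on the raw parameter
scale. An F-test (larger variance in the numerator, two-sided) at
α = 0.05 gates the choice between the pooled and the Welch t-test per
parameter; 0.05 mirrors the global significance convention, since no gate
threshold is conventionally fixed. No multiple-testing correction is
applied across the seven parameters — the emulated report publishes raw
per-parameter p-values. Note that percent change on the raw scale can be
counterintuitive for sign-carrying parameters (a skewness moving from
−0.906 toward −0.729 is a raw *increase* toward zero); the report carries
the signed value and leaves interpretation to the reader.

Under the null (both arms generated from the control law) the per-parameter
type-I error of the gated procedure is nominal; the acceptance suite
verifies a rejection rate compatible with 0.05 over 200 replicate cohorts.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own trade-off between fidelity and a fast,
deterministic check set:

* worked examples: exact 256-level computations (no sampling);
* direction-of-effect cohort: the full default geometry, 7 + 7 specimens
  at ≈ 2.1×10⁵ shell voxels each, delineated at threshold 1 — synthetic
  background and canal are exactly 0, so this reproduces the exact
  cortical compartment, the analogue of a contoured ROI. (A high threshold
  would instead truncate the skew-normal's low-intensity tail, and
  truncate the control arm's heavier tail more, biasing third moments:
  threshold choice matters on real data too.);
* parameter recovery: one specimen with ≥ 2×10⁵ shell voxels, asserting
  the targets within 0.5 (mean), 0.3 (sigma) and 0.1 (skewness) — wide
  Monte-Carlo bands relative to the moment-estimator sampling SDs at that
  size;
* null calibration: 200 replicate 7 + 7 cohorts on a reduced shell
  (≈ 3.4×10³ voxels per specimen); the type-I error of the comparison
  does not depend on voxel count, so the small geometry changes nothing
  being tested.

## Known limitations

* First-order statistics only: co-occurrence, wavelet or fractal texture,
  and BMD calibration to physical units are out of scope.
* The approach presumes dense, compact tissue; in trabecular bone,
  partial-volume blending suppresses intensities and the histogram no
  longer reflects tissue density, so these parameters are not recommended
  there.
* Published p-values for the real cohort are not recoverable from rounded
  group summaries, and the published dispersion column is ambiguous; the
  package reproduces the report's *structure* and directional findings,
  not its exact inferential numbers.
* All results depend on the scanner's attenuation-to-gray mapping; only
  cohorts scanned and reconstructed identically should be compared.
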