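---
title: "Fingerprinting cortical grey matter from HARDI profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting cortical grey matter from HARDI profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

High angular resolution diffusion imaging (HARDI) acquires one
diffusion-weighted volume per encoding direction at a fixed b-value — here 61
directions at b = 1000 s/mm² plus one b = 100 s/mm² reference. In cortical
grey matter the directional dependence of this signal is subtle but
reproducible, and it carries information about the local arrangement of
myelinated fibres (radial and tangential populations). `hardigm` turns that
dependence into a per-vertex tissue *fingerprint* and asks whether the
fingerprint discriminates cortical regions.

The pipeline is surface-based. From each vertex of the inner (GM/WM)
surface, the local normal **n** is followed to mid-thickness (halfway to the
pial surface) and a single trilinear sample per DWI is taken there, giving
61 intensities plus a reference per vertex. The log transform

$$ f(u) = -\tfrac{1}{b}\,\log\!\big(S(u)/S_0\big) $$

yields per-direction apparent diffusion coefficient (ADC) samples, to which
an even-order real spherical-harmonic (SH) series up to order 6 is fit by
ordinary least squares (28 coefficients $a_{ki}$; 61 directions
overdetermine the fit). Odd orders are excluded because diffusion
measurements are antipodally symmetric — the even-only basis is also what
makes the 27-feature count come out (see below).

### The 27 features

Seven families are computed from the fitted profile $f$ and the local
normal **n**; families 1, 2 and 7 are invariant under any rotation of the
data, families 3–6 are referenced to **n** and invariant only when the data
and the normal rotate together:

1. `mean_sphere` — $\bar f = \frac{1}{4\pi}\int_S f \, dS$.
2. `mom_sphere_k2..k10` — central moments
   $\mu_k = \frac{1}{4\pi}\int_S (f-\bar f)^k dS$, $k = 2..10$.
3. `adc_normal` — $f(\mathbf n)$, diffusivity along the cortical normal.
4. `mean_perp` — mean of $f$ over the unit circle $C(\mathbf n)$
   perpendicular to **n** (in-plane diffusivity).
5. `mom_perp_k2..k10` — central moments of $f$ on $C(\mathbf n)$.
6. `hess_eig1`, `hess_eig2` — the two eigenvalues (descending) of the
   Hessian of $f$ on the sphere at **n**; curvature of the profile,
   sensitive to fibre-orientation dispersion.
7. `shpow_k0..k6` — per-order SH power $P_k = \sum_i a_{ki}^2$ for
   $k = 0, 2, 4, 6$, the standard rotation invariants of each order.

That is $1 + 9 + 1 + 1 + 9 + 2 + 4 = 27$ values per vertex, in the fixed
order returned by `feature_names()`.

Two of these definitions were genuinely open design choices. The moment
families are *central* moments normalized by the domain measure: central
moments decouple profile shape from profile mean, so family 2 does not
re-encode family 1 (raw moments are available via `central = FALSE`). The
order-power family is the sum of squared coefficients per order, the
simplest complete rotation invariant of each order (an RMS-amplitude
variant is available via `sqrt_variant`). Both choices are forced, up to
convention, by requiring 27 values with the stated invariance partition.

### Discrimination

For supervised experiments the two repeats of a test/retest acquisition act
as independent train and test sets: a radial-basis SVM (cost 1, kernel
width $1/27$, the off-the-shelf libsvm defaults) is trained on the repeat-1
feature vectors of the labeled regions and evaluated on the unseen
repeat 2. Features are z-scored with *training* statistics only — the 27
entries span many orders of magnitude (mm²/s means vs. squared SH powers),
and without standardization the large-scale entries dominate the kernel.
Pairwise region comparisons report the *balanced* rate, the mean of the two
per-region correct fractions, so a 100:1 size imbalance cannot masquerade
as discrimination; `pairwise_matrix()` demonstrates chance-level (50%)
balanced rates for identical distributions at any imbalance.

Unsupervised parcellation uses k-means (k-means++ seeding, fixed seed) on
standardized features; cluster ids are relabeled along a short chain
through the cluster centres (greedy nearest-neighbour from the most
extremal centre, 2-opt refined — the open-path objective is NP-hard, so
this is a documented heuristic with its objective value reported), which
makes parcellation maps colorable on one scale. `intrinsic_dimension()`
reports how many principal components reach 95% variance; on phantom data
this lands around 7–10, consistent with substantial redundancy in the 27
features.

## The synthetic phantom

No scan data accompany the analysis, so `build_phantom()` generates the
study conditions: two repeats of a 61-direction acquisition over a folded
two-surface cortical ribbon with known class labels.

* **Geometry.** The inner surface is a regular sheet (default 1 mm vertex
  spacing) folded sinusoidally, z = A sin(2πx/λ) with A = 7 mm, λ = 40 mm,
  so surface normals span well over 90° — class membership cannot be read
  off orientation, which is exactly the confound the
  orientationally-referenced features must remove. The outer surface is the
  inner surface displaced 3 mm (mid-range human cortical thickness) along
  the analytic normal.
* **Microstructure.** Each class is a mixture of Gaussian tensor
  compartments resolved against the local normal. The default library holds
  a radial-dominant class (70% stick-like tensor, eigenvalues
  (1.2, 0.2, 0.2)·10⁻³ mm²/s, along the normal + 30% isotropic
  0.8·10⁻³), a tangential-dominant class (the same stick lying in the
  cortical plane) and a fully isotropic class (0.8·10⁻³). These emulate
  plausible radial/tangential myelinated-fibre contrasts; they are a
  stand-in for real cortex, not a claim about it.
* **Rasterization.** Voxels (1 mm isotropic by default) whose centers fall
  within the ribbon carry the noise-free signal of their nearest
  mid-thickness vertex; outside the ribbon an isotropic free-water-like
  background (3.0·10⁻³ mm²/s) applies. On a flat unit-spacing ribbon the
  vertex grid aligns with voxel centers, so mid-thickness sampling
  reproduces the simulated class signals exactly — the analytic round-trip
  the sampling tests rely on.
* **Noise.** Magnitude-MRI Rician noise,
  $\sqrt{(S+\varepsilon_1)^2+\varepsilon_2^2}$, with σ set from a
  reference-signal SNR of 20 (typical for 3T DWI at this resolution; the
  acquisition's true SNR is not published). The two repeats share the
  noise-free volume and differ only in noise seeds, so SNR = ∞ makes them
  bit-identical.
* **Drift.** B0 drift appears in real acquisitions as a slow translation
  along the phase-encoding direction; `drift_correct()` applies the
  incremental counter-translation (volume j moves by j·T/68) used to cancel
  it. The phantom does not simulate drift (nor eddy currents, distortion or
  motion, which the original workflow corrects with external tools), so the
  correction is validated by construction: identity at T = 0, exact
  arithmetic on linear fields, round-trip on smooth fields.
* **Smoothing.** Surface-based iterative neighbour-mean smoothing stands in
  for the nearest-neighbour resampling used on real data, whose exact
  operator is unpublished; it is calibrated by its impulse-response FWHM
  instead. One iteration on the 1 mm fixture mesh gives 1.78 mm, matching
  the 1.8 mm kernel of the emulated preparation.

### What the phantom does and does not show

Passing the phantom experiments shows that the feature chain preserves and
exposes class-specific directional structure through sampling, noise, fit
and classification — with classes this distinct at SNR 20, the three-way
train-on-repeat-1 / test-on-repeat-2 SVM reaches ~100% (the real-data
analogue reported 80–82% across three subjects, against which a synthetic
rate of at least that order is the meaningful check). It does *not* show
that real cortical areas are so separable: real regions differ far more
subtly, partial-volume and registration errors are worse, and ROI
definitions are themselves noisy.

One consequence of the phantom's design is worth stating plainly: its
classes are internally *homogeneous* (one tensor mixture per class), so
all reproducible feature variation lies between classes. Unsupervised
k-means with more clusters than classes must therefore subdivide
homogeneous blobs, and those subdivisions follow the noise realization,
which is independent across repeats — measured between-repeat adjusted
Rand agreement at k = 10 is ~0.4–0.55 regardless of restarts, while
clustering the *same* repeat twice agrees at ~0.97. Real cortex, by
contrast, has reproducible within-region heterogeneity for k-means to lock
onto, which is what makes whole-hemisphere parcellation at k = 40
reproducible on real data. A homogeneous-class phantom cannot reproduce
that behaviour at realistic SNR; the package reports the ARI honestly
rather than inflating the phantom's within-class structure to force it.

## Numerical choices

* **Sphere quadrature.** Feature integrals use a Gauss–Legendre (cos θ) ×
  uniform-azimuth product rule, 36 × 72 = 2592 points by default. This rule
  integrates spherical polynomials exactly up to degree 71, which covers
  the 10th power of an order-6 expansion (degree 60), so the Gram matrix of
  the 28 SH basis functions is the identity to ~1e-15 and all moment
  integrals are exact to roundoff. A vertex-weighted icosphere of similar
  size was measured at only ~2.5e-3 orthonormality error and was rejected.
  Circle integrals use 360 uniform angles (trapezoid rule on a periodic
  integrand: exact below frequency 360).
* **In-plane basis.** The circle C(**n**) is parameterized from the
  component of the global x-axis orthogonal to **n** (y-axis fallback when
  |n·x| > 0.99); all in-plane features are provably independent of this
  choice and tested as such.
* **Hessian.** Central finite differences on the sphere with tangent step
  h = 1e-3 rad, points re-projected to the unit sphere, plus Richardson
  extrapolation over h and h/2. Plain central differences at this step
  leave a ~1e-6 relative truncation error whose size depends on the
  tangent basis, which is both above the accuracy target for the
  single-tensor oracle and large enough to break co-rotation invariance at
  the 1e-7 level; extrapolation removes the leading term (oracle error
  ~8e-10, co-rotation variation ~3e-8).
* **Log-transform floor.** Signals are clamped to max(S, 1e-6·S₀) before
  the log — the Rician floor, drift resampling or interpolation can
  produce non-positive apparent signals — and clamp counts are reported.
  Negative *fitted* ADC values are deliberately left alone in the feature
  integrals so the moments stay unbiased.
* **Least squares.** Plain OLS via QR, with rank checking; a ridge option
  (`ridge_weight`, never shrinking the mean term) exists for noisy data but
  is off by default. Degenerate inputs fail loudly: under-determined
  direction sets, rank-deficient bases, non-unit directions, mismatched
  gradient tables.
* **Determinism.** All randomness flows through explicit integer seeds
  (phantom noise per repeat, gradient-layout rotation, k-means++ draws),
  and all writers emit fixed numeric formats, so identical configurations
  reproduce outputs byte-for-byte.
* **Problem sizes.** The standard experiment uses 3 classes × 500 vertices,
  61 directions and two repeats (~3,000 fitted profiles); it runs in under
  a minute on one CPU, and the bundled test suite uses the same scale for
  end-to-end checks with smaller ribbons (60–180 vertices) for unit-level
  geometry tests.

## Limitations

* The reference image is b = 100, not b = 0, so ADC values carry a small
  uniform bias exactly as in the emulated acquisition; since every vertex
  shares it, classification is unaffected.
* Single-shell, single-depth sampling: no multi-shell microstructure
  models, no multi-depth laminar profiles (the record layout and the
  `fraction` argument leave room for the latter).
* The phantom provides co-registered inputs by construction; inter-repeat
  registration, motion/eddy/distortion correction and surface
  reconstruction are upstream, external-tool territory.
* SVM kernel and parameters of the original analysis are unpublished; the
  libsvm-era defaults used here are exposed in the configuration.
* Mesh I/O is ASCII OFF only; FreeSurfer binary surfaces, GIFTI/CIFTI and
  DICOM are out of scope.
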