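---
title: "Methods: from deep organoid stacks to multiscale tissue fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from deep organoid stacks to multiscale tissue fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepvox)
```

deepvox turns multi-channel two-photon stacks of dense, multi-layered 3D
samples (gastruloids, organoids, spheroids) plus nuclear instance
segmentations into quantitative tissue-scale maps. This vignette explains the
models behind each stage, the parameters that matter, the numerical choices,
and what the synthetic phantoms do and do not establish about real data.

## The measurement model

A detected channel is modelled as

\[ I(\vec x) \;=\; M_{\mathrm{inst}}(\vec x)\, S(\vec x)\, A(\vec x) +
\varepsilon(\vec x), \]

where \(M_{\mathrm{inst}}\) is the binary mask of signal instances (nuclei),
\(S\) the biological expression field, \(A\) the optical artifact field, and
\(\varepsilon\) additive noise. Two artifact families are corrected
explicitly:

* **Spectral cross-talk**: each fluorophore bleeds into several detector
  channels; in scattering tissue the apparent emission pattern
  \(p_i^k(z)\) (fraction of fluorophore \(i\)'s signal in channel \(k\))
  drifts with depth because absorption is wavelength dependent.
* **Depth decay**: to first order \(A(\vec x,\lambda) = e^{-z/d(\lambda)}\)
  with a wavelength-dependent decay length \(d\). Decay lengths scale
  multiplicatively across imaging conditions, so the ratio
  \(r(\lambda_2,\lambda_1) = d(\lambda_2)/d(\lambda_1)\) depends only on the
  two wavelengths.

## Spectral unmixing

Patterns are calibrated per depth bin (default 10 µm, fine enough to resolve
the 100–200 µm decay-length scale while keeping dozens of planes' worth of
voxels per bin) from single-fluorophore acquisitions:
`calibrate_patterns()` takes masked per-channel means and normalizes across
channels. Gain changes transfer by column-rescaling and renormalization
(`interpolate_gain()`).

Filters are \(F = (P^{\top} D P)^{-1} P^{\top} D\) with
\(P[k,i]=p_i^k\) and \(D = \mathrm{diag}(1/\langle I^k\rangle)\); they are
*unbiased*, \(\sum_k f_i^k p_j^k = \delta_{ij}\), which the tests assert to
1e−10 for random valid patterns. `compute_filters()` refuses pattern
matrices whose scaled condition number exceeds 1e6: beyond that, unmixing
amplifies noise past usefulness. Unmixing itself is the per-plane linear map
\(I_i = \sum_k f_i^k(z) I^k\); filters are applied piecewise-constant per
bin, with optional linear blending between bin centres (`blend = TRUE`).
Negative unmixed intensities are legitimate noise excursions and are
preserved; saturated voxels are counted and reported, never masked.

## Dual-view registration and fusion

Samples imaged from both sides of a flipped slide are paired by stage
position with an exact linear-assignment solve (`pair_views()`), then
registered rigidly: the slide flip is the preset 180° rotation about X
(`rigid_flip_x()`), matched landmarks give the optimal rotation by SVD with
reflection correction (`fit_rigid_landmarks()`), and an optional
coarse-to-fine grid search over residual Euler angles (±15°, step 2.5°,
scored by masked normalized cross-correlation) covers the residual flip
errors of order 10° seen in practice (`refine_rigid()`). Trilinear
interpolation resamples intensities; nearest-neighbour resamples labels.

Fusion weights the two views by depth, because each view's SNR decays away
from its own objective. On the overlap coordinate mapped to [0, 1],

\[ f_1(z) = \frac{1}{1 + e^{p (z - z_0)}}, \qquad f_2 = 1 - f_1 , \]

with slope \(p = 15\) and inflection \(z_0 = 0.5\) by default, giving decay
length \(l = 4/p = 0.27\) and effective fusion width \(\delta = 2l = 0.53\)
of the overlap. Mapping the overlap to [0, 1] makes these settings
independent of overlap size. Outside the overlap the single valid view
passes through unweighted.

## Masked Gaussian coarse-graining

All tissue-scale fields come from one engine: convolution with a normalized
Gaussian of physical size σ (µm), truncated at \(a = 3\sigma\). The masked
variant divides by the smoothed mask,

\[ I^{\sigma,M} = \frac{k_\sigma * (I\,M)}{k_\sigma * M}, \]

which prevents the artifactual decay of the signal near mask boundaries and
lets a nuclear quantity be evaluated over the whole sample. The sparse
variant is the same formula with the mask concentrated at scattered
positions (per-nucleus values at centroids); neighbours within \(3\sigma\)
are found through a uniform bucket-grid spatial index, and queries with no
in-range support are flagged `NA` rather than extrapolated.

Numerical choices:

* The truncated kernel is renormalized to unit sum (per axis), so constants
  are preserved exactly; at array borders the dense variant renormalizes by
  the in-image kernel mass. Consequence: the impulse-density field integrates
  exactly to the object count only for objects with full interior kernel
  support.
* Anisotropic voxels are handled by expressing the kernel in µm.
* Validity threshold: a masked estimate is `NA` where the denominator is
  below 1e−3 of the kernel peak.
* σ below half a voxel returns the input with a warning.

**Boundary bias.** Within one kernel radius of the sample's border the
masked average samples the depth gradient asymmetrically (only inward
neighbours exist), which biases estimates of decaying signals. This is
inherent to the estimator, not a bug; the same reasoning leads to fitting
decay profiles in a *central column* and to computing flatness statistics on
*bulk* planes (≥ 3σ from the first/last signal plane) in the test suite.

## Intensity normalization

Assuming the reference nuclear stain (Hoechst) is homogeneous, its masked
Gaussian average over nuclei estimates \(S_{h,0} A(\vec x)\)
(`reference_field()`). A target channel at wavelength \(\lambda_b\) is
corrected as \(\hat I_b = I_b / (I_h^{\sigma,M_{\mathrm{nuc}}})^{r}\) with
\(r = d(\lambda_h)/d(\lambda_b)\) (`normalize_channel()`). The orientation of
\(r\) is easy to invert accidentally; the package locks it with a phantom
oracle: `estimate_ratio_loglog(target, reference)` — the slope of
\(\log I_{\mathrm{target}}\) on \(\log I_{\mathrm{ref}}\) over signal
voxels — returns exactly the exponent to apply to the reference field. With
decay lengths 100 µm (blue) and 208 µm (far red), \(r = 0.48\), the order
measured for Hoechst against far-red nuclear stains.

Decay lengths themselves are fitted by nonlinear least squares of per-plane
masked means against \(A e^{-z/d}\) in a central column (25 % of the sample
radius), initialised from the log-linear fit and short-circuited to it when
that fit is already exact (zero-residual data makes `nls`'s convergence test
degenerate). Non-decaying profiles return `d = Inf` as a "no decay"
sentinel.

The smoothing scale σ is selected by `select_sigma()`: for each candidate
the reference is normalized by its own field (r = 1) and the σ minimising
the MAD of per-plane medians is chosen (ties to the smallest). The candidate
grid default is 5–30 µm in steps of 5 µm; in practice values around the
nucleus diameter (10–15 µm) behave well. On noiseless phantoms this
objective decreases monotonically as σ shrinks (the field tracks the signal
ever more closely), so the tests assert the contract — argmin of the
reported curve, tie-break, and that normalizing at the selection flattens
the profile — rather than a specific optimum.

`rescale_global()` restores cross-sample comparability: one multiplicative
factor transmits the median raw reference intensity of the brightest region
(top decile of the reference field, restricted to signal voxels) to the
normalized reference. Samples differing only by a staining factor then agree
exactly on their normalized marker channels.

## Abundance fields and morphometrics

Density (impulses at centroids, masked-smoothed, per µm³), volume fraction
(smoothed binary mask, in [0, 1]) and volume maps (sparse average of
per-object volumes) describe local abundance at any scale; division density
over cell density gives the local proliferation probability. Detections are
filtered by minimum volume and in-sample centroid before mapping. The
inside-sample mask is derived from the nuclei channel: light denoising
(1 µm), Otsu threshold, closing at two nucleus radii, 3D hole filling,
largest component, and a 1.5 µm border allowance for the cytoplasmic rim
beyond the outermost nuclear surfaces.

Per-nucleus shape uses the inertia tensor
\(I_{ij} = \sum_k (\delta_{ij} r_k^2 - r_{k,i} r_{k,j})\) in physical
coordinates; for a uniform ellipsoid the semi-axes follow from the principal
moments as \(L_i^2 = \tfrac{5}{2N}(I_1+I_2+I_3-2I_i)\). The *true strain*
tensor, \(T_i = \tfrac13 \log\!\big(L_i^3/(L_1L_2L_3)\big)\) reassembled in
the principal frame, is trace-free and size-independent, so averaging it
across nuclei does not over-weight large ones. Degenerate objects (< 4
voxels, coplanar, or non-positive moment bracket) are flagged and excluded
from averaging; nuclei with near-degenerate elongation
(\(T_1 - T_2 < 0.02\)) are flagged `axis_stable = FALSE` because their major
axis is numerically meaningless.

The alignment field averages \(\cos^2\theta\) between each nucleus's strain
major axis and the local cell-density gradient (central differences on the
σ-smoothed density, same σ as the averaging — the axis sign cancels in
\(\cos^2\), and averaging the scalar avoids the sign ambiguity entirely).
Values near 1/0 mean deformation parallel/perpendicular to the gradient;
isotropic orientations average exactly 1/3. Nuclei whose gradient is zero
(or below a caller-set norm) are excluded and counted: where the gradient is
packing noise, the angle carries no information.

## Expression analysis

Normalized channels are binned per nucleus (mean over label voxels); cells
are called positive per marker by Otsu thresholding of the per-cell
distribution over a 256-bin histogram. Tie-break: between well-separated
modes the between-class variance is flat across the empty gap, and the
middle cut is taken so the threshold sits centrally between the modes.
Positive-fraction maps divide positive-cell density by total cell density;
radial profiles bin any field by the anisotropic Euclidean distance to the
sample border; co-expression quadrants partition cells by the two marker
thresholds, reporting counts, per-quadrant cell ids (for spatial
back-mapping) and Pearson/Spearman correlations overall and among
double-positives. Correlations are intended for *normalized* intensities;
the CLI refuses raw channels without `--allow-raw`.

## The phantom generator

`phantom_spec()`/`generate_phantom()` build the study conditions every test
runs on: non-overlapping ellipsoidal nuclei rejection-packed into a sphere
(volume fractions up to the random-close-packing regime; measured aggregates
reach ~0.61), per-nucleus log-normal brightness (the real distribution is
not tightly constrained; log-normal is configurable via
`brightness_sdlog`), marker classes with known radial Bernoulli laws, a
mitotic flag (5 % by default), channels mixed through a known matrix and
decayed per channel (defaults 100/140/170/208 µm, blue to far red, giving
the 0.48 blue:far-red ratio), additive Gaussian noise, and a second view
generated by transforming the geometry under a known rigid flip (plus a
residual rotation of order 10°), re-rasterizing, and re-applying decay from
the opposite face — so no double interpolation touches the ground truth.

Two generator behaviours deserve note. A dense tangential *wall layer* is
placed before bulk packing (`wall_layer = TRUE`): aggregates present a
packed, tangentially flattened outer cell layer, and without it the nuclear
envelope tapers several µm inside the nominal boundary, which no mask recipe
could recover. Beware of scale: on a desk-scale sphere (radius ~30 µm with
4.5 µm nuclei) the wall band holds most of the volume, so a covered wall
consumes most of a 0.3 packing budget and the interior packs sparser — a
property of small spheres, not of real-sized aggregates (at radius 150 µm
the band is only ~25 % of the volume). For constructions needing a strict
radial placement law (density steps), disable the wall layer. Second,
`orientation = "tangential"` elongates all nuclei perpendicular to the local
radius, giving the alignment field a known perpendicular ground truth.

What the phantoms do *not* emulate: realistic PSFs, scattering beyond the
first-order exponential, segmentation errors (labels are exact by
construction), lumens/cavities, or camera noise beyond additive Gaussian.
Passing tests therefore establish the correctness of the computations on
idealized optics and geometry — not segmentation robustness on real images.

## Problem sizes and determinism

Test phantoms use spheres of radius 16–30 µm at 1 µm isotropic voxels
(roughly 90–100 nuclei at volume fraction 0.3), a scale at which every
stage, including the end-to-end dual-view pipeline, runs in seconds while
leaving dozens of populated depth bins and planes. All generator randomness
flows through one seeded local RNG (`with_seed()`), restored on exit, so a
fixed seed is bit-reproducible and the global RNG state is never touched.
Macros record explicit seeds per step and replay bit-identically on
identical inputs.

## Known limitations

* Masked-smoothing estimates within one kernel radius of the sample border
  are boundary-extrapolated and biased on gradients (see above); flatness
  and decay statistics should be read on bulk planes / central columns.
* The exponential decay model is first order; residual geometry-dependent
  artifacts (the second-order term of the artifact field) are left in the
  data and not fitted.
* `select_sigma()`'s homogeneity objective cannot distinguish artifact from
  signal at scales below the nucleus; candidate grids should start around
  the nucleus diameter.
* The block-matching style refinement is a coarse grid search over rotations
  only; strongly non-rigid deformation between views is out of scope.
* Density and proliferation maps do not exclude hollow structures (lumens)
  unless a cavity mask is supplied.
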