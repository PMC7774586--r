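---
title: "Laminar grey-matter intensity analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar grey-matter intensity analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`laminargm` measures cortical grey-matter (GM) T1-weighted-like signal as a
function of cortical depth, removes the trends that local curvature and
thickness impose on it, aggregates it over probabilistic atlas regions at mid
cortical depth, and compares groups with a participant-level mixed model.
This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic phantoms do and do not emulate,
and the numerical decisions taken where the design was genuinely open.

## 1. The depth coordinate

Cortical depth is a normalized coordinate from 0 at the WM–GM interface to 1
at the GM–CSF interface. The package computes two maps.

**Equidistant depth** is `ρ = d_wm / (d_wm + d_csf)`, where `d_wm` and
`d_csf` are the distances (mm) from the voxel centre to the two interfaces.
It is exact for flat cortex and biased wherever the cortex bends: layers keep
their *volume* fraction, not their distance fraction, so over a gyral crown
the deep layers occupy more of the distance range than of the volume.

**Equi-volume depth** corrects this with a frustum model of the local
cortical traverse. With mean curvature `H` (1/mm, positive where the surface
bulges toward CSF) and the two interface distances, the bounding surface
areas are taken proportional to `(1 − H·d_wm)²` on the WM side and
`(1 + H·d_csf)²` on the CSF side, and the returned depth is

$$\alpha \;=\; \frac{-A_{csf} + \sqrt{(1-\rho)\,A_{csf}^2 + \rho\,A_{wm}^2}}
{A_{wm} - A_{csf}},$$

clamped to [0, 1], reducing to ρ when the areas are equal. On a spherical
shell with interface radii $r_1 < r_2$ the exact volume-fraction depth of a
voxel at radius $r$ is $(r^3 - r_1^3)/(r_2^3 - r_1^3)$; the frustum model is
an approximation to it (at $\rho = 0.5$ on a 7–10 mm shell it gives 0.417
against the exact 0.413), accurate to well under the discretization error at
the working resolution. Depth clamping beyond 0.05 raises a warning, because
out-of-range values indicate segmentation problems rather than numerical
ones.

### Distance fields from binary labels

Tissue labels quantize the interfaces at half-voxel scale, and per-voxel
distance transforms inherit that noise (≈ ±0.1 mm at 0.7 mm voxels, which
would dominate the depth error budget on a 3 mm ribbon). The package
therefore measures distances in three steps:

1. **Face-point distance transform.** The interface is localized at the face
   between differing labels. Face midpoints are rasterized on a 2×
   supersampled grid and an exact Euclidean distance transform (compiled,
   Felzenszwalb–Huttenlocher separable algorithm, anisotropic spacing) gives
   the unsigned distance of every voxel centre to each interface. A GM voxel
   whose neighbour is WM is exactly half a voxel from the WM–GM interface.
2. **Field-level anti-aliasing.** The signed distances are combined into the
   depth-fraction field `ρ̂ = φ_wm / (φ_wm + φ_csf)` and the thickness field
   `τ̂ = φ_wm + φ_csf`. For parallel interfaces ρ̂ is a linear ramp and τ̂ is
   constant *over the whole grid*, so Gaussian smoothing (σ = 1 voxel,
   tunable as `sigma_vox`) suppresses the label staircase without biasing
   either field; the residual curvature-induced bias of ρ̂, proportional to
   `σ²H/τ`, is subtracted using the measured curvature.
3. **Re-expansion.** `d_wm = ρ̂·τ̂` and `d_csf = (1 − ρ̂)·τ̂`, clamped at 0.

**Mean curvature** is `H = ½ ∇·(∇ψ/|∇ψ|)` of the mid-surface level set
`ψ = (ρ̂ − 0.5)·τ̂`, evaluated with central differences, followed by a second
Gaussian pass on the curvature field itself (σ = 1.5 voxels,
`sigma_curv_vox`). Curvature is a second derivative of a quantized field:
without that second pass its per-voxel noise is ~25% of `1/r` on an 8.5 mm
sphere; with it, ~4%, at the cost of attenuating curvature variation on
scales below ~2 voxels — far below the wavelength of cortical folds. Voxels
whose stencil is truncated by the grid border, or where the gradient
magnitude falls below 0.3, are imputed from their nearest valid neighbours
and counted in a message.

These choices were validated against the shell oracle: median equi-volume
depth error is ~0.011–0.014 depth units across shells with inner radii 5, 7
and 9 mm at 0.7 mm voxels, against an equidistant bias of 0.05–0.08, and the
error decreases monotonically from 1.0 to 0.7 to 0.5 mm voxels.

## 2. Intensity preparation

**Resampling** is trilinear on the cell-centred world grid implied by the
original field of view; the new grid has `ceiling(extent/spacing)` samples
per axis and out-of-extent positions clamp to the edge (so no zeros are
introduced near the mask boundary). Nearest-neighbour resampling is provided
for label volumes.

**Bias-field normalization** models the multiplicative inhomogeneity as
`exp(P(x))` with `P` a polynomial of total degree 3 (`order`) in world
coordinates, fitted by least squares to the log intensity *within a
homogeneous reference region* — in this pipeline the WM mask. Fitting inside
a region that is constant up to bias is what makes the operation safe: a fit
over the whole brain would absorb genuine anatomy (the laminar profile
itself) into the "bias". The field is normalized to unit log-mean over the
reference region and divided out of the whole volume; the operation is
idempotent to numerical precision and requires strictly positive intensities
inside the reference region. The pipeline runs it twice — before and after
brain-mask application — mirroring the usual order of normalize, strip,
re-normalize; the second pass is a no-op on phantoms but kept as the default
pipeline structure (`two_pass_normalization`).

**Detrending** is a single global OLS fit of GM intensity on
`[1, curvature, thickness]` per participant (not per lobe), with residuals
z-scored by their own mean and SD. The z-map is therefore centred on the
individual's average GM signal: values above 0 mean higher-than-average
T1-w contrast. Degenerate inputs fail loudly: an exact linear fit (zero
residual SD) and collinear regressors (condition number above 1e8, reported)
are errors, because both invalidate the z-scale downstream. Note that a flat
slab is *by construction* degenerate — its curvature and thickness are both
constant — which is why detrending demonstrations use the folded phantom
with thickness modulation.

## 3. ROI aggregation

For each ROI the selected voxels are GM voxels with

* probability strictly greater than the 25% quantile (`prob_quantile`) of
  the ROI's strictly positive probabilities, computed with the
  linear-interpolation ("type 7") quantile rule, and
* equi-volume depth inside `[0.4, 0.6]` (`depth_window`), endpoints
  inclusive.

Three conventions were fixed by decision where the rule admitted readings:
the quantile is taken over the positive support only (zeros outside an ROI's
extent say nothing about it); the window endpoints are inclusive; and the
probability threshold is strict. The selection is monotone: lowering the
quantile or widening the window can only grow it. Voxels may contribute to
several overlapping ROIs; no exclusivity is imposed. Rows whose selection is
empty carry missing features, are counted in a message, and are excluded
from modelling.

The 70-region gyral parcellation metadata shipped in
`inst/extdata/dk_rois.tsv` (35 labels per hemisphere) carries the package's
own lobe assignment of each region to frontal, parietal, temporal or
occipital; cingulate regions are split between frontal and parietal, and the
insula is counted as temporal.

## 4. Group inference

The feature table is modelled as
`outcome ~ group * lobe + hemisphere + age + gender` with a participant
random intercept, fitted by REML with `nlme`, and fixed terms are tested
with sequential conditional F-tests (containment denominator df — the
convention of that implementation; a Satterthwaite alternative via
`lmerTest` is available through `ddf = "satterthwaite"`). Age is centred and
gender enters as a factor, so the intercept is the control reference. Only
the group × lobe interaction is included beyond additive covariates; fuller
interaction sets were considered and rejected as the default because the
regional hypothesis lives in that single term and additional interactions
cost power at these sample sizes.

Per-lobe follow-up models are linear models on ROI-level rows with
participant-clustered (CR) standard errors — the unit-of-analysis choice is
genuinely open, so a participant-mean alternative (`unit = "participant"`)
is provided and both are exercised in the tests. P-values are corrected
across the four lobes within each group-contrast family, Bonferroni by
default (`holm` and `BH` accepted). Post-hoc tests are two-tailed Welch
t-tests on participant-level ROI means. Covariate-adjusted correlations
residualize both the participant-level outcome and the external score on
age and gender and report the partial r with a t-based two-sided p.

Monte-Carlo calibration under the null (3 groups of 20, 16 ROIs in 4 lobes,
intercept SD 0.3, residual SD 0.5, 500 replicates) puts the interaction
test's type-I error near 0.06 at α = 0.05 with an approximately uniform
p-distribution; these are the problem sizes used throughout the test suite,
chosen to make the Monte-Carlo bands tight while keeping a full run in
minutes on one CPU.

## 5. What the phantoms emulate — and what they do not

`make_phantom` builds three geometries with exact voxel-centre labels
(no partial-volume fractions, so ground truth stays analytic):

* **slab** — flat ribbon, the zero-curvature limit; interfaces fall on voxel
  faces so depth and thickness have closed forms;
* **shell** — spherical ribbon; depth truth is the volume fraction, curvature
  truth `1/r`, thickness `r₂ − r₁`;
* **folded** — mid-surface `z = a·sin(2πx/λ)` extruded along y with normal
  offsets ±T/2, optionally with thickness modulated sinusoidally *across*
  traverses (`thickness_mod_amplitude_mm`), giving sign-varying curvature
  truth and an identifiable thickness regressor.

Intensity is `bias(x) · (profile(depth) + c_H·H + c_T·T + offsets + ε)`,
with a laminar profile that by default decreases with depth (deep,
WM-adjacent cortex brightest, as myelination makes real T1-w cortex), a
multiplicative `exp(quadratic)` bias field (positive by construction),
Gaussian voxel noise (default SD 0.1 in intensity units whose GM contrast
range is ≈ 0.6), and optional regional offsets used to inject group effects.
Cohort-level structure (participant random intercepts, group × lobe offsets,
age and gender distributions matched to a young, predominantly female
help-seeking cohort: age ≈ N(22, 4.2²), 70% female; group sizes defaulting
to 49/114/39) is layered on top either directly at the feature-table level
(`simulate_cohort`) or through per-participant phantom volumes
(`simulate_cohort_volumes`).

Injected offsets are specified in z units and scaled into raw intensity by
the phantom's predicted detrended GM SD. Because z-scoring centres each
participant on their own GM mean, a regional offset is only identified
*relative to the rest of the cortex*: the package therefore measures
recovery with `lobe_differential_effect` (target lobe minus other lobes,
contrasted between groups), which is also what the group × lobe interaction
estimates. On the packaged six-participant folded cohort the injected −0.5
frontal offset is recovered within two participant-level standard errors.

The phantoms deliberately do **not** emulate: MR pulse-sequence physics,
motion or ghosting artefacts, partial-volume mixing at interfaces,
segmentation errors (labels are ground truth — the real pipeline's
dependence on segmentation quality is out of scope of these tests), cortical
topology (no handles or crossings), or spatially varying noise. A passing
test suite therefore certifies the *computational* chain, not robustness to
acquisition artefacts.

## 6. Numerical and design decisions, collected

* Interfaces live on faces between differing labels; distances are measured
  from voxel centres to faces (half-voxel convention), via a supersampled
  face-point distance transform.
* Smoothing scales: `sigma_vox = 1` voxel for the depth/thickness fields,
  `sigma_curv_vox = 1.5` voxels for the curvature field; both in voxel units
  so behaviour is resolution-invariant.
* Equi-volume formula orientation fixed so that a voxel at the equidistant
  midpoint of a convex shell maps *below* 0.5 (toward the smaller inner
  volume).
* Quantile rule: type 7 over positive support; depth window inclusive;
  probability threshold strict.
* Mixed model: REML; containment df default; Bonferroni across lobes per
  contrast family.
* Iso-surfaces by tetrahedral decomposition (six tetrahedra per cell, linear
  edge interpolation), meshed in world coordinates; cells touching
  background are not meshed, so open phantom boundaries do not generate
  spurious sheets. Export as ASCII PLY.
* All millimetre quantities flow through the affine; voxel indices are
  0-based in world mappings; volumes round-trip through NIfTI via the sform
  (the quaternion form cannot carry anisotropic scaling faithfully here).
* Every stochastic element is seeded; cohort generators derive
  per-participant seeds from the cohort seed, and two runs from the same
  configuration are bit-identical.

## 7. Known limitations

* The frustum area model uses mean curvature only; strongly anisotropic
  folds (two very different principal curvatures) are approximated.
* Curvature smoothing attenuates genuine curvature variation below ~2 voxel
  wavelengths; on real, tightly folded cortex at coarse resolution this
  underestimates extreme curvatures.
* The per-voxel geometric accuracy quoted here is phantom-based; real
  segmentations add errors that the phantoms by design exclude.
* The bias-normalization polynomial is global; it cannot represent
  high-frequency coil inhomogeneity, and extrapolation far outside the
  reference region is only as good as a cubic can be.
* `simulate_cohort` draws thickness independently of the z-GM outcome; joint
  structure between thickness and intensity deficits is not emulated.
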