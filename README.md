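# laminargm

Laminar grey-matter (GM) intensity analysis on cortical phantoms.

## The problem

T1-weighted MRI signal inside the cortical ribbon carries information about
myelin and iron content, and group differences in that signal — rather than
in volume or thickness alone — are of interest in, for example, psychosis-risk
cohorts. Measuring it well requires a chain of spatial steps that are easy to
get subtly wrong: the cortex must be parameterized in a depth coordinate that
respects cortical folding, the intensity must be freed of the trivial trends
that curvature and thickness impose on it, and regional averages must be taken
at a controlled depth before any group model is fitted. None of the published
end-to-end pipelines expose these steps in a form that can be validated
against ground truth.

`laminargm` implements the full chain in R and validates every stage on
synthetic cortical phantoms (flat slabs, spherical shells, folded ribbons)
whose depth, curvature, thickness and injected group effects are known
analytically. It is aimed at researchers who run laminar ROI analyses of
anatomical MRI and want each stage testable in isolation.

## The model

**Equi-volume depth.** For a GM voxel with distances `d_wm` and `d_csf` to the
WM–GM and GM–CSF interfaces, the naive (equidistant) depth is
`ρ = d_wm / (d_wm + d_csf)`. In curved cortex ρ is biased: deep layers
thin over gyral crowns and thicken in sulci. The equi-volume map converts ρ
into the fraction of local cortical *volume* below the voxel using a frustum
model, with bounding surface areas inferred from the local mean curvature `H`
and thickness `T` (`A ∝ (1 ∓ H·d)²`):

```
α = (−A_csf + √((1−ρ)·A_csf² + ρ·A_wm²)) / (A_wm − A_csf)
```

which reduces to ρ when `A_wm = A_csf` (flat cortex). On a spherical shell
with radii `r₁ < r₂` the true depth of a voxel at radius `r` is the volume
fraction `(r³ − r₁³)/(r₂³ − r₁³)`; this closed form is the package's oracle.

**Curvature.** `H = ½ ∇·(∇ψ/|∇ψ|)` of the signed distance field ψ to the
mid-cortical surface, positive toward CSF (gyral crown); `1/r` on a sphere.

**Intensity features.** Per participant, GM intensity is regressed on
`[1, H, T]` by OLS; the residuals are z-scored over GM (mean 0, SD 1 — the
individual T1-w average is the reference). For each probabilistic atlas ROI,
GM voxels with probability above the 25% quantile of the ROI's positive
support and depth in `[0.4, 0.6]` are averaged into one row per
participant × ROI.

**Group inference.** The long table is modelled as

```
mean_z_gm ~ group * lobe + hemisphere + age + gender + (1 | participant)
```

by REML (`nlme`), with conditional F-tests per fixed term; per-lobe linear
models contrast each group against the control intercept with
participant-clustered standard errors and Bonferroni correction across lobes;
post-hoc two-tailed Welch t-tests and covariate-adjusted partial correlations
complete the toolkit.

## Worked example

```r
library(laminargm)

## geometry accuracy on a spherical-shell phantom with analytic depth
spec <- phantom_spec("shell", inner_radius_mm = 7, outer_radius_mm = 10,
                     spacing_mm = 0.7, noise_sd = 0)
ph  <- make_phantom(spec)
geo <- laminar_geometry(ph$labels)
gm  <- ph$truth$gm_mask
round(c(equivolume  = median(abs(geo$depth$data[gm] - ph$truth$depth$data[gm])),
        equidistant_bias = median(geo$depth_equidistant$data[gm] -
                                  ph$truth$depth$data[gm])), 4)
#>       equivolume equidistant_bias
#>           0.0138           0.0722
```

The equi-volume map tracks the analytic volume fraction to a median error of
0.014 depth units, while the equidistant baseline is biased by 0.072 toward
the CSF side — the folding artefact the equi-volume model exists to remove.

```r
## a simulated 202-participant cohort with a -0.5 z-GM deficit in the
## frontal lobe of the CHR group, analysed with the mixed model
eff    <- data.frame(group = "CHR", lobe = "frontal", offset = -0.5)
cohort <- cohort_spec(n_per_group = c(control = 49, CHR = 114,
                                      `CHR-negative` = 39),
                      effect_by_lobe = eff, seed = 1)
tab <- simulate_cohort(cohort, dk_atlas_meta())
fit_group_lme(tab, reference_group = "control")
#> Linear mixed model for mean_z_gm (202 participants, 14140 rows; reference 'control')
#> Random intercept SD 0.3134, residual SD 0.5019
#> Conditional F-tests (containment df):
#>          term numDF denDF         F         p
#> 1 (Intercept)     1 13928 7.126e+01 0.000e+00
#> 2       group     2   197 1.645e+01 2.479e-07
#> 3        lobe     3 13928 1.737e+03 0.000e+00
#> 4  hemisphere     1 13928 7.432e-06 9.978e-01
#> 5       age_c     1   197 2.819e+00 9.474e-02
#> 6      gender     1   197 3.956e-01 5.301e-01
#> 7  group:lobe     6 13928 1.317e+02 0.000e+00
```

The simulated variance components (0.3 / 0.5) are recovered, and the
group × lobe interaction — the test that carries the regional hypothesis —
is strongly significant. The per-lobe follow-up localizes it:

```r
per_lobe_contrasts(tab)[1:4, c("lobe", "contrast", "estimate", "t", "p_corrected")]
#>        lobe                contrast    estimate           t  p_corrected
#> 1   frontal          CHR vs control -0.55942684 -10.8684640 3.100165e-21
#> 2   frontal CHR-negative vs control -0.02682442  -0.3730168 1.000000e+00
#> 3 occipital          CHR vs control -0.05520576  -0.9753484 1.000000e+00
#> 4 occipital CHR-negative vs control -0.01925300  -0.2416602 1.000000e+00
```

Only the frontal CHR contrast survives Bonferroni correction, with an
estimate near the injected −0.5.

A complete volumetric run — phantom cohort, bias-field normalization,
masking, laminar geometry, detrending, ROI extraction and group statistics —
is one call: `run_pipeline(run_config(out_dir = "run1", seed = 7))`. A thin
command-line front end with `simulate`, `prep`, `geometry`, `features`,
`stats` and `run` subcommands is installed at `inst/cli/laminargm.R`.

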