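---
title: "3D cross-sectional morphometry of sperm storage tubules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D cross-sectional morphometry of sperm storage tubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstmorph)
```

## The measurement problem

Sperm storage tubules (SSTs) are blind-ended epithelial tubules in the
utero-vaginal junction (UVJ) of the avian oviduct. Their 3D shape — in
particular whether the orifice is constricted relative to the rest of the
tubule, and whether the cross-section is circular or elliptical — bears
directly on how sperm enter, are retained in, and leave storage. Light-sheet
(SPIM) imaging of live UVJ tissue resolves individual SSTs label-free,
because punctate autofluorescent granules in the supranuclear epithelium
outline each tubule.

Measuring cross-sectional diameters from such stacks is not a 2D problem:
SSTs follow convoluted paths through the mucosal fold, so a fixed-axis slice
cuts most tubules obliquely and overestimates their diameter by a factor
$1/\cos\theta$. The pipeline in this package therefore:

1. averages two manually traced *side traces* (orifice → blind end, opposite
   sides of the lumen) into a luminal **centerline**;
2. parameterizes the centerline by arc length and samples it at $N$
   equidistant points ($N = 10$ by default, the first at the orifice, the
   last at the blind end);
3. estimates the local tube direction at each sample by central differences
   on neighboring sample points, and extracts a 2D section **normal to that
   direction** by trilinear interpolation from the undilated stack;
4. measures on each section the major and minor axis diameters $d_1 \ge d_2$
   of the region enclosed by autofluorescence, via the moment-equivalent
   ellipse of the thresholded, hole-filled component at the slice centre;
5. models the repeated measures per bird with linear mixed-effects models.

The two response summaries follow the field's convention: the **mean
diameter** $(d_1 + d_2)/2$ and the **circularity index** $d_1/d_2$ (1 =
circular, larger = elliptical).

## Statistical models

Let $y_{ij}$ be the mean diameter of bird $i$ at sampled arc-length distance
$s_{ij}$ from the orifice, and $L_i$ the tubule's total length. The diameter
model is

$$ y_{ij} = \beta_0 + \beta_1 s_{ij} + \beta_2 s_{ij}^2 + \beta_3 L_i +
   b_i + \varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2),\;
   \varepsilon_{ij} \sim N(0, \sigma^2), $$

fitted by REML with a random intercept per bird (repeated measures). A
negative $\hat\beta_2$ with positive $\hat\beta_1$ describes the observed
shape: constricted at the orifice, widest near the midpoint. The circularity
model regresses $d_1/d_2$ on total length, the diameter magnitude
$d_1 + d_2$, distance, and the $(d_1+d_2)\times$ distance interaction, with
the same random-effect structure.

Inference uses **Satterthwaite** degrees of freedom. Because the target
environment provides `lme4` but not `lmerTest`, the Satterthwaite
approximation is implemented in-package: the asymptotic covariance of the
REML variance-component estimates is obtained by finite differences of the
(dense) REML criterion, and each coefficient's df is
$2 f^2 / (\nabla f^\top A \nabla f)$ with $f$ the coefficient's sampling
variance as a function of the variance components. The tests validate this
path against an independent profiled-REML oracle implemented in the test
helpers, and the type-I error of the resulting p-values is checked by
simulation (KS uniformity under the null).

Variance explained is reported as Nakagawa–Schielzeth $r^2$:
$r^2_m = \sigma_f^2 / (\sigma_f^2 + \sigma_b^2 + \sigma^2)$ and
$r^2_c = (\sigma_f^2 + \sigma_b^2) / (\sigma_f^2 + \sigma_b^2 + \sigma^2)$,
with $\sigma_f^2$ the variance of the fixed-effect predictions.

**Distance scale.** The source analyses report a single "estimated effect"
for the quadratic term without stating the distance units, which fixes the
magnitude of that coefficient. `fit_diameter_model()` therefore exposes
`distance = "um"` (raw micrometres, the default) and `"normalized"`
(distance divided by tubule length, the scale on which the synthetic
generator states its quadratic, so parameter recovery is exact), plus raw
vs. orthogonal-polynomial parameterizations. Estimates are comparable across
parameterizations only through the fitted curve, not coefficient by
coefficient.

**Lumen extrapolation.** Epithelial cells keep an approximately constant
cross-sectional thickness as the tubule widens, so lumen diameter scales
linearly with outer diameter. `fit_lumen_scaling()` is ordinary least
squares on paired (outer, lumen) observations and `predict_lumen()` applies
the line — this is how orifice lumen calibre is inferred from the
autofluorescence envelope.

## The synthetic stated world

`make_measurement_table()` and `render_sst()` generate data with known
ground truth. Their defaults are *statements about the modelled system*,
fixed once from the published morphology and not tuned afterwards:

* diameter profile $d(s) = 10.1 + 25.2 s - 25.2 s^2$ µm on normalized
  $s \in [0,1]$: orifice 10.1 µm, widest section 16.4 µm at the midpoint;
* ellipticity 1.6 (SD 0.2, split 0.1 bird-level / 0.173 residual), drawn
  independently of every covariate so the circularity model's null holds;
* epithelium thickness 3.4 µm: half the difference between the reported
  autofluorescence (10.1 µm) and lumen (3.3 µm) orifice diameters;
* bird-intercept SD 2.86 µm and residual SD 4.35 µm, chosen so the
  *population* variance partition reproduces the reported
  $r^2_m = 0.1584$, $r^2_c = 0.4123$ at the study design (10 birds × 10
  points). The finite-sample $r^2_m$ *estimator* at that design runs
  $\approx 0.03{-}0.05$ high, which the acceptance report shows honestly;
* tubule length $\sim N(300, 80^2)$ µm truncated at 120 µm — the study does
  not print lengths; this is a field-plausible choice for zebra finch SSTs;
* no true length effect on diameter or circularity (the study found none);
* granule σ 0.75 µm (sub-micron, lysosome-like), intensity 100, density
  250 granules per µm of tubule length (≈ 20 per µm length per µm diameter):
  dense enough that the punctate shell reads as continuous, as in the source
  images. Granules sit in the epithelial shell between the lumen surface and
  the envelope $d(s)$, never in the lumen interior, and overhang both tubule
  ends by one epithelium thickness (the blind end is capped by epithelium
  and the orifice joins the surface epithelium), so end sections see a full
  shell;
* noise: Poisson shot noise on signal plus background (rate 2) and Gaussian
  read noise (SD 1) — the standard fluorescence model; the study does not
  characterize its noise.

What the generator deliberately does **not** emulate: light-sheet optics
(PSF anisotropy beyond voxel spacing, stripe artifacts), tissue scattering,
branched tubules, sperm inside the lumen, or any spatial structure in
granule brightness. A green synthetic test therefore establishes that the
*geometry and estimation chain* is correct at realistic noise levels — not
that segmentation would survive every real-tissue artifact.

## Numerical choices

* **Coordinates.** Physical micrometres everywhere; arrays are `(nx, ny,
  nz)` with voxel centres at `(i − 0.5)·spacing` (R is column-major, so the
  x-fastest layout is the natural one here; TIFF pages remain z-slices).
* **Interpolation.** Trilinear (order 1): monotone, never overshoots around
  punctate granules; out-of-volume pixels are filled with 0 and flagged in a
  validity mask so measurement knows which pixels are extrapolated.
* **Slice geometry.** The in-plane frame is deterministic:
  `u = normalize(n × e)` with `e` the global axis least parallel to `n`
  (ties broken x, y, z), `v = n × u`. In-plane pixel spacing defaults to the
  smallest voxel spacing (no invented resolution); half-width defaults to
  30 µm, covering the widest reported sections.
* **Thresholding.** Otsu by default, applied twice: a global pass finds the
  component at the slice centre, then the threshold is re-estimated within
  that component's 3 µm-padded bounding window and the segmentation redone.
  The second pass removes a field-of-view artefact: with a fixed 30 µm
  half-width the background fraction depends on tubule calibre and biases a
  single global Otsu by up to ~1 voxel at d = 30 µm. A fixed absolute
  threshold (`"fixed:<value>"`) is available for sensitivity analysis.
* **Robustness ladder.** If the shell fails to close around the slice
  centre (noisy, fragmented sections), measurement retries at 2× and 4× the
  smoothing sigma before raising "tube not found at slice center".
* **Moments.** `d1`, `d2` are `4√λ` of the eigenvalues of the region's
  second central moment matrix, plus the `spacing²/12` single-pixel term so
  rasterized shapes measure at true size (a disk of radius R gives exactly
  2R). A max/min Feret caliper estimator is available as `method = "feret"`.
* **Averaging traces.** Sides are paired by normalized arc length after
  dense resampling (default 200 points) — parameter-free and symmetric; the
  sampling operation is exactly idempotent only on straight polylines and
  drifts < 0.1 µm per reapplication on densely sampled smooth curves.
* **Tangents.** "Nearest neighboring points" is read as immediate
  neighbors: central differences at interior samples, one-sided at the two
  ends.
* **The 10th point.** The last sample is placed at the blind end itself
  (s = L); the alternative reading ("just before the blind end") is
  supported by resampling the trace short of its final vertex before
  calling `measure_sst()`.
* **Degenerate fits.** Tables that are an exact linear function of the
  predictors (zero residual and zero random-intercept variance) would break
  `lmer`; the fitters detect near-zero OLS residual variance and return the
  exact OLS coefficients with zero variance components, df and p set to NA,
  and $r^2$ at its limit.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
## a gently convoluted 150 um tubule rendered into a SPIM-like volume
cl   <- make_centerline(seed = 1, total_length = 150, tortuosity = 0.25)
cfg  <- render_config(volume_shape = c(200, 120, 60),
                      voxel_spacing = c(1, 1, 1.5), seed = 1)
cl   <- center_in_volume(cl, cfg)
geom <- sst_geometry(cl)            # profile 10.1 + 25.2 s - 25.2 s^2, e = 1.6
ren  <- render_sst(geom, cfg)
tr   <- simulate_side_traces(ren$ground_truth, jitter_sd = 0.5, seed = 2)

rec  <- measure_sst(ren$volume, tr$side_a, tr$side_b)
rec$measurements[, c("s_um", "d1_um", "d2_um", "mean_diameter_um")]

## cohort-level inference on a simulated 10-bird study
tab <- make_measurement_table(seed = 1)
fit_diameter_model(tab, distance = "normalized")
```

## Known limitations

* Envelope measurements on punctate shells carry ~5–10% apparent
  ellipticity on single sections even for truly circular tubes; circularity
  is best interpreted per tubule (averaged over sections), which is how the
  statistical model uses it.
* The measured envelope of a granular shell has an intrinsic boundary
  uncertainty of roughly half the granule σ; diameter biases are below one
  voxel across the 6–30 µm calibre range, but not zero.
* The Satterthwaite implementation covers the single-random-intercept
  models used here; it is not a general mixed-model inference engine.
* Branched tubules are out of scope (the traces define a single path), and
  tracing itself is an input — the package does not segment tubules from
  the volume.
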