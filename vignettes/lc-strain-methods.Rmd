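---
title: "Measuring lamina cribrosa strain from radial OCT with FI-DVC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lamina cribrosa strain from radial OCT with FI-DVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcstrain)
```

## The measurement problem

The lamina cribrosa (LC) is the porous connective-tissue plate in the optic
nerve head through which retinal ganglion cell axons leave the eye, and the
principal site of glaucomatous axonal injury. When intraocular pressure
(IOP) rises acutely, the LC deforms; how much it deforms per mm Hg — its
*compliance* — is a candidate biomechanical marker of glaucoma
susceptibility. This package implements the image-analysis half of that
experiment: given a pair of radial optical coherence tomography (OCT) scan
sets of the optic nerve head acquired before and after an IOP change,
together with manually marked landmarks and the measured pressure change,
it estimates the three-dimensional displacement field of the LC by
fast-iterative digital volume correlation (FI-DVC), converts it to
cylindrical Green–Lagrange strains, summarises them over the LC analysis
region, measures the anterior lamina depth (ALD) change relative to
Bruch's membrane opening (BMO), and divides strains by the IOP increase to
obtain compliances.

No clinical images ship with the package. Instead a first-class phantom
module generates synthetic radial speckle volumes with *analytically known*
deformations, so that every stage — and the pipeline end to end — is
validated against closed-form ground truth.

## Scan geometry and coordinate conventions

A session consists of `n_scans` radial B-scans crossing a common axis,
`angular_step` degrees apart, with `n_scans * angular_step = 180`: each
scan is a full diameter, so the half-turn of scan planes tiles the full
circle. The device geometry is 24 scans every 7.5°, 768 × 495 px per scan,
3.87 µm/px in depth and 5.33–6.94 µm/px laterally; at the BMO margin the
gap between adjacent scans is about 108 µm of arc, which is the effective
circumferential resolution.

Volumes are stored as `(i_r, scan, i_z)` arrays. Internally the lateral
coordinate is the *signed* radius along each scan
(`r = (i_r - scan_center) * res_r`); the `r < 0` half of the scan at angle
θ covers en-face direction θ + 180°. Stepping past the last scan re-enters
the first scan mirrored — the scan-index axis is periodic with period
`2 n_scans`, and across that wrap the lateral axis reverses, so the stored
in-plane vector components change sign. All interpolation, correlation and
differentiation code uses this one convention; the standard cylindrical
strain formulas remain valid with signed radius, which is why it is used
everywhere. Reported shear components are mapped back to the outward-radial
basis so both halves of a scan agree.

Pixels are 1-based at pixel centres; depth `z = (i_z - 1) * res_z`.

## Preprocessing

Scans are contrast-enhanced by contrast-limited adaptive histogram
equalization (CLAHE, via EBImage) followed by a gamma correction of 1.75
(`round(255 * (v/255)^1.75)`). Tile count and clip limit are not dictated
by the acquisition protocol; the defaults (8 × 8 tiles, clip fraction 0.01
of a flat tile histogram) were fixed once by inspecting the phantom
baseline-error sweep — settings that minimise zero-strain error — and are
configurable. Whether gamma precedes or follows CLAHE is also configurable
(`gamma_first`); the default applies CLAHE first. On phantoms,
preprocessing leaves the registered displacement unchanged to within
0.2 voxel, which is the property that matters for strain.

## Segmentation

Manual landmarks per scan are the two BMO endpoints and ≥ 5 anterior LC
border points. The border is interpolated piecewise-linearly and extended
to the lateral borders; the analysis region is bounded laterally by
verticals through the BMO endpoints, anteriorly by the border, and
posteriorly by a curve 250 µm posterior to it. Because "parallel, 250 µm
posterior" is ambiguous for tilted borders, the default offsets each border
point along its local normal (constant separation); a pure depth offset is
available behind a flag. The central zone is the en-face disc of half the
BMO diameter (radius `bmo_diameter / 4`) about the BMO centre; quadrants
split on the ±45° diagonals about the nasal–temporal axis, with the
boundary assigned to the vertical sectors and nasal/temporal mirrored
between right and left eyes. Zone and quadrant membership is decided
per-pixel in en-face coordinates. Membership in depth is half-open
(`z_anterior <= z < z_posterior`), which at 3.87 µm/px makes a flat
250 µm region 64–65 rows deep.

## FI-DVC registration

The registration follows the fast-iterative DVC scheme: divide both
volumes into a grid of overlapping subsets, cross-correlate each subset
pair under a Gaussian window, accumulate the displacement increment
`u^k = u^{k-1} + du^k`, warp the deformed volume back through the
cumulative field, halve the subset size, and repeat. Defaults: subsets
64 × 8 × 64 voxels halving in-plane to 16 × 8 × 16 (the scan-index extent
stays at 8 because only 24 samples exist on that axis), 50% overlap, 3
iterations, Gaussian window with σ = subset/4. The window tapers subset
edges so high-spatial-frequency content survives windowing; the iteration
removes the residual peak-shrinkage bias that windowed correlation has at
large shifts. Volumes are correlated as true anisotropic 3-D arrays —
including across scans — rather than per-plane, because a single
convention handles all three displacement components at once; at radii
where adjacent scans decorrelate the circumferential component simply
carries little signal and wide uncertainty, as it does for the real
instrument.

Numerical details worth knowing:

* Subset extraction uses a floor-based lattice so half-integer grid
  centres never duplicate rows (duplicated rows in both subsets inject a
  spurious zero-lag correlation that biases displacements toward zero).
* The correlation peak is searched within ±subset/4 of zero lag; the
  subpixel offset is a separable 3-point Gaussian fit (parabolic when any
  of the three samples is non-positive), ties broken toward the smaller
  lag, clamped to ±0.5 voxel.
* `q` is the windowed normalized cross-correlation value at the peak;
  zero-variance subsets get `q = 0` and are invalid.
* The increment grid of each iteration is interpolated onto the final
  (finest) grid, so the returned field is exactly the sum of its recorded
  increments.
* Pixel displacements convert to µm through the geometry; the
  circumferential component uses the local signed radius
  (`U_theta = du_scan * r * dtheta`), and grid points with `|r|` below
  half the final in-plane subset extent are invalid (axis singularity).
* Convergence stops early when the largest increment falls below 0.05
  voxel (replicate pairs converge in one iteration).

On phantoms this recovers a 19.35 µm axial translation to better than
0.1 µm and a 0.5% uniform strain ramp with a relative error of a few
percent.

## Validity filtering

Four filters, applied in a fixed order so outliers are judged against
already-cleaned neighbours; each is idempotent and only shrinks the valid
set, and removal counts are logged:

1. **Correlation threshold**: `q < 0.055` excluded (threshold
   configurable so a different `q` definition can be recalibrated).
2. **Displacement error** (5 µm ceiling): the estimator is
   forward–backward consistency,
   `e(x) = 0.5 |u_fwd(x) + u_bwd(x + u_fwd(x))|`, chosen because it needs
   no ground truth; the ceiling applies to the magnitude.
3. **Edges**: grid points within one grid step of the lateral/depth image
   borders (the scan-index axis has no edge).
4. **Outliers**: any component deviating from its valid 3 × 3 × 3
   neighbourhood median by more than 3 neighbourhood MADs *and* more than
   one voxel.

`percent_area_correlated()` reports the fraction of region grid points
that survive, the coverage statistic quoted with clinical results.

## Strain computation

The displacement field is smoothed by a moving local least-squares
quadratic fit (a 3-D Savitzky–Golay smoother) over the valid neighbours
within a window of radius 2 grid points; quadratic reproduction means
constant and linear fields — hence uniform strains — pass through
unbiased, while white displacement noise variance drops by well over
four-fold. Points with fewer than 12 valid neighbours are invalidated
rather than extrapolated.

The displacement gradient is formed by central differences on the grid
(circumferential derivatives across adjacent scan planes, spacing
`r dtheta`, periodic across the half-turn with the sign-flip convention),
including the cylindrical curvature terms `-u_theta / r` and `+u_r / r`,
and the finite-strain tensor is `E = (H + H' + H'H)/2`. The quadratic term
makes rigid motion give exactly zero strain — verified to 10⁻⁶ for a 5°
rotation about the axis. In-plane principal values follow from the 2 × 2
R–Z submatrix:

* `E_max = (E_rr + E_zz)/2 + sqrt(((E_rr − E_zz)/2)² + E_rz²)`
* `Gamma_max = sqrt(((E_rr − E_zz)/2)² + E_rz²)` — the *tensorial*
  maximum shear (half the principal-strain difference). The engineering
  convention (twice that) is available behind a flag. The tensorial
  choice is consistent with cohort tables in which the mean maximum shear
  slightly exceeds the mean maximum principal strain, as happens when the
  second principal strain is strongly negative.

Negative strains are contractions, positive expansions. Points lacking a
full valid difference stencil are dropped, not one-sided. Region
summaries are plain valid-point means and SDs for the full LC, the
central/peripheral zones and the four quadrants.

## ALD change

For every border point, `ALD = U_z(border) − U_z(BMO line)`, the BMO-line
axial displacement interpolated linearly between the two endpoints'
displacements; positive is posterior (deeper). Sampling is
validity-aware; an endpoint falling in a filtered-out cell falls back to
the nearest valid grid point of that scan within 200 µm, and a scan with
no usable endpoint is omitted with a warning. The overall value is the
mean over all valid border points pooled across scans. By construction
the measure cancels global axial motion, which phantoms with superposed
10 µm translations confirm.

## Phantoms: what they emulate and what they do not

`generate_speckle_volume()` builds a band-limited random-phase speckle
field — a sum of ~200 cosine plane waves with isotropic wave vectors
concentrated near spatial frequency 1/grain — evaluated at the physical
position of every voxel and quantised to 8 bits after a percentile
contrast stretch. This form was chosen over a blurred-noise lattice
because it is a continuous function of position: the texture is
consistent across neighbouring scans of the radial pattern and the same
field can be evaluated anywhere, keeping phantom deformation free of
grid artefacts. A layered intensity envelope (dim prelaminar tissue, a
bright 300 µm lamina band below the border profile, intermediate below)
gives the correlation-threshold filter something realistic to reject.
The default grain is 15 µm at device resolution (twice the finest pixel
pitch is the resolvability floor).

Deformations are defined in physical coordinates with exact inverses and
Jacobians: translation, uniform stretch (engineering strains; the
Green–Lagrange value is `e + e²/2`, so a 0.5% target uses
`e = −1 + sqrt(1 − 0.01) ≈ −0.499%`), rigid rotation (exactly zero
strain), a smoothstep depth shift that moves the lamina while the BMO
stays put, and compositions. Warping resamples through the inverse map
with cubic in-plane / linear across-scan interpolation; the identity map
returns the input bit-exactly.

The phantoms deliberately do *not* simulate OCT physics: no vessel
shadowing, no depth attenuation, no enhanced-depth-imaging artefacts, and
the speckle statistics are calibrated only so DVC succeeds, not to match
clinical contrast. Passing phantom tests therefore demonstrates the
correctness of the measurement chain, not clinical image quality
robustness.

The cohort generator embeds the compliance structure directly:
`strain = (compliance + md_effect × MD) × ΔIOP + noise`, with ΔIOP
uniform on 3–16 mm Hg, MD uniform on −12 to +1.4 dB, residual strain SD
0.0013 (the scale of repeat-imaging baseline error), and default
compliances equal to the cohort-mean strains divided by the mean
7.1 mm Hg pressure rise. The default MD effect is zero except a small
negative slope on the axial-circumferential shear compliance
(−2 × 10⁻⁵ per dB per mm Hg), i.e. more positive shear compliance with
worse field damage. VFI and RNFL co-vary with MD with realistic means and
spreads; they are conveniences for exercising the regression plumbing,
not a disease model.

## Error analysis and statistics

`baseline_error()` runs the full pipeline on back-to-back replicate
volumes (optionally noise-perturbed at a chosen SNR) and reports
per-component means and SDs — the zero-strain reproducibility floor.
`correlation_error()` repeats a known deformation over independent
phantom realisations and reports bias and RMSE against the closed-form
truth. `exceeds_baseline()` compares cohort-mean strains against the
baseline mean with a two-sided one-sample t-test at α = 0.05. The
clinical analysis this mirrors uses generalized estimating equations to
absorb inter-eye correlation; that is routine statistics outside this
package's scope, so the in-package tests and `cohort_summary()`
regressions are ordinary one-sample/OLS procedures with that caveat
documented, and `write_cohort_csv()` exports records for external GEE
modelling.

## Problem sizes used in tests

Unit tests run on a reduced radial geometry (12 scans every 15°,
128 × 96 px at 12 / 7.74 µm per pixel, 32 × 4 × 32 subsets halving to
16 × 4 × 16) where a registration takes a few seconds. The end-to-end
validation suite and the acceptance script use a downsampled session
geometry of 384 × 24 × 248 voxels at 12 / 7.74 µm per pixel with 30 µm
grain and the default correlation schedule; one registration then takes
about half a minute, a full forward-plus-backward pipeline about two.
The known-strain sweep uses 5 phantom realisations in the acceptance
script and 2 in the test suite; the type-I-error simulation uses 200
null cohorts of 20 eyes.

## Known limitations

* The circumferential displacement is poorly constrained at large radius
  (adjacent scans ~108 µm apart against a ~15–30 µm speckle grain), so
  `E_tt` and the θ-shears carry the widest uncertainty — visible in the
  phantom SDs.
* Strains are computed only where the field is valid; removed regions are
  never inpainted, so region means are means over the correlated subset
  of the LC.
* One-sample t-tests and OLS ignore inter-eye correlation.
* The smoothing scheme, the outlier rule's exact parameters, and the `q`
  definition follow this package's stated conventions; all are exposed in
  configuration objects so alternative conventions can be recalibrated
  against the phantom suite.

## A worked phantom example

```{r example, eval = FALSE}
g <- radial_scan_geometry(n_scans = 24, n_r = 384, n_z = 248,
                          res_r = 12, res_z = 7.74)
ref <- generate_speckle_volume(g, grain_size = 30, seed = 1)
e <- -1 + sqrt(1 - 2 * 0.005)      # engineering ramp for E_zz = -0.005
pair <- apply_deformation(ref, deformation_uniform_strain(e_zz = e))
lm <- make_lc_landmarks(g, bmo_diameter = 1750)
res <- lc_pipeline(ref, pair$deformed, lm)
res           # region means: e_zz near -0.005, shears near zero
tidy(res)     # the summary tibble
autoplot(res$strain, component = "e_zz", scan = 1)
```
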