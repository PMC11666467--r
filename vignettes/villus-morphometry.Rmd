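---
title: "Measuring intestinal villi in 3D: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intestinal villi in 3D: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Whole-mount confocal stacks of cleared small-intestinal mucosa show a carpet
of finger-like villi rising from a crypt layer. The absorptive capacity of
the gut scales with villus length, volume and surface area, and these
quantities change dramatically in physiological adaptations such as
pregnancy and lactation. Quantifying them from a 3D stack requires four
steps, each of which this package implements as a separately testable
operation:

1. **Crypt masking.** The crypt region is annotated manually on a handful of
   2D slices and interpolated into a 3D mask; subtracting it leaves the
   villus foreground and defines the *base surface* where villi meet crypts.
2. **Instance segmentation.** The villus foreground is split into individual
   villi: iterative erosion plus Laplacian-of-Gaussian (LoG) filtering
   produces one seed object per villus, and the seeds are regrown over the
   full foreground by marker-controlled watershed.
3. **Morphometry.** Per instance: length as the maximum of a geodesic
   distance map seeded at the villus base, volume as voxel count times voxel
   volume, surface area by a Crofton line-grid estimator (with a
   triangulated-mesh estimator as cross-check), and cross-section flatness
   from per-slice covariance eigenvalues.
4. **Cohort statistics.** Per-sample tables aggregate to group summaries
   (mean ± s.e.m., median, IQR) and comparisons (Welch *t*, one-way ANOVA
   with Tukey HSD), computed both per villus and per animal.

All computations run in physical micrometre units on the anisotropic voxel
grid. Confocal whole-mount stacks are strongly anisotropic — a z-step of
2.15 µm against sub-micrometre pixels is typical — so voxel-count morphology
would be directional; every erosion, dilation and distance in this package
is defined through exact Euclidean distance transforms in µm.

## The synthetic phantom and its analytic truth

No suitable public 3D dataset with per-villus ground truth exists, so the
package ships a generator for two-channel mucosa phantoms with closed-form
morphometry. A phantom is a floor slab plus crypt layer (thickness
`floor_thickness + crypt_layer_depth`) with capsule-shaped villi standing on
it. Each villus has a shaft of length $L_c$ with elliptical cross-section of
semi-axes $(a\,r,\ r/a)$ and a half-ellipsoid tip with vertical semi-axis
$r$, giving

$$L = L_c + r,\qquad
V = \pi r^2 L_c + \tfrac{2}{3}\pi r^3,\qquad
S = P(a r,\ r/a)\,L_c + S_{\mathrm{cap}},$$

where $P$ is the ellipse perimeter (complete elliptic integral of the second
kind) and $S_{\mathrm{cap}}$ the half-ellipsoid area (numerical quadrature,
relative tolerance $10^{-9}$). The flattening parameter $a \ge 1$ preserves
the cross-section area $\pi r^2$, so flattening changes shape without
changing volume — this isolates geometric flattening (as observed for the
expanded villi of lactating animals) from growth. The expected covariance
flatness of a filled ellipse with semi-axes $(a r, r/a)$ is the axis ratio
$a^2$.

Rendering is deliberately simple: the actin-like channel is background 10,
tissue interior 110 and a one-voxel cortical shell at 140 detector counts;
the nuclei-like channel is a 2% random speckle inside the tissue. Both are
blurred with an anisotropic Gaussian point-spread function and perturbed
with additive Gaussian read noise (default sd 5), then rounded to integer
counts. The shell is kept close to the interior intensity on purpose: a
much brighter rim would shift the half-maximum crossing of the blurred edge
outward and bias every downstream volume and surface estimate (we measured
roughly +4% villus volume at shell 200 versus +1% at 140). The phantom
emulates the features the pipeline's operators actually consume — solid
objects with realistic shape, an anisotropic PSF, detector noise, a crypt
layer — and deliberately omits depth attenuation, spherical aberration,
villus branching and staining heterogeneity. Passing the acceptance
criteria therefore demonstrates correctness of the *operators*, not
robustness to every artefact of real microscopy.

All randomness flows from a single `rng_seed`; identical specs render
bit-identical volumes.

### Default geometry

Real mouse villi are roughly 20–40 µm in radius and 200–600 µm long; the
generator's defaults (`phantom_spec`) reflect that scale. The standard
validation phantom (`validation_phantom_spec`) uses geometrically similar
but smaller villi (r = 8–12 µm, L = 90 µm, twenty villi at (1, 0.5, 0.5) µm
spacing, ~9 million voxels), because every validated property — instance
counts, relative errors, scaling laws, group contrasts — is scale-free,
while memory and time are cubic in linear size. The vignette states this as
the package's own choice of validation problem size.

## Design choices in the segmentation stage

The seeding loop is the one stage where the classical description ("binary
operations and LoG filtering used iteratively") admits many concrete
realizations; ours is fully parameterized by `seeding_params` and logged per
run:

* at iteration $k$ the mask is eroded by a ball of radius
  $k \cdot$ `erosion_step` (a threshold of the exact anisotropic distance
  transform);
* the LoG of the distance transform (not of raw intensity: seeds should
  reflect object *shape*, one blob per finger, not staining texture) is
  evaluated at scale `sigma_schedule[min(k, last)]`;
* every 26-connected component of the eroded mask containing at least one
  regional maximum of the sign-flipped LoG response becomes a seed;
  components below `min_seed_volume` are dropped;
* the loop stops when the seed count is stable over two consecutive
  iterations, when erosion empties the mask, or at `max_iterations`, and
  returns the labelling with the *most* seeds (latest occurrence). The last
  rule matters: erosion past the thinnest villus half-width can only lose
  instances, so "return the last labelling" would silently drop slender
  flattened villi (for $a = 2$, $r = 8$ µm the minor half-width is 4 µm,
  which a 2-µm-per-iteration erosion crosses at $k = 2$).

Marker regrowth assigns every mask voxel to the seed with the smallest
within-mask geodesic distance — the marker-controlled watershed of the
geodesic distance field. We chose the geodesic elevation over the negated
Euclidean distance transform because it makes the partition exactly
checkable against an independent shortest-path oracle, is deterministic,
and respects in-tissue connectivity for curved villi. Ties are broken by
(smaller distance, then smaller seed label, then smaller linear index), and
output labels are renumbered 1..N by descending volume.

### Exact arithmetic for determinism

Geodesic edge lengths are quantized to integer multiples of
$2^{-20}\max(\mathrm{spacing})$ (about one part in $10^6$) and accumulated
in 64-bit integers. Path sums are therefore exact, ties are exact, the
tie-break is reproducible across platforms and algorithms, and uniform
spacing changes rescale every distance exactly — which is what makes the
scaling-law and oracle-equivalence tests meaningful at tolerance $10^{-12}$
rather than "within float noise".

## Estimator choices in the morphometry stage

**Length** is geodesic (within-object), not Euclidean: for tilted or curved
villi a straight-line distance map would cut through the lumen and
underestimate length. A Euclidean variant is available for sensitivity
analysis (`length_metric` in the CLI). No half-voxel end corrections are
applied; the resulting bias (about half a z-step on a ~90 µm villus, ~1%) is
far below the validation tolerances and keeps the implementation exactly
equal to its oracle.

**Surface area** defaults to the Crofton line-grid estimator with the 13
discrete directions of the 26-neighbourhood, the semantics of the standard
label-analysis toolchain for this measurement. Direction weights are
calibrated at run time by non-negative least squares so that the discrete
Cauchy projection kernel $\sum_d w_d\,|u_d \cdot n|$ is as uniform as
possible over surface normals $n$ (deterministic Fibonacci sphere sampling).
On isotropic grids this lands near the classical spherical-partition
weights; on anisotropic grids, where the physical directions crowd toward
the coarse axis, partition-area weights underestimate vertical extruded
shapes by about 6% at 2:1 anisotropy, while the calibrated weights stay
within ~1% on digitized spheres and capsules. Axis-aligned boxes remain
underestimated by ~10% — an inherent limitation of 13-direction line grids —
for which the mesh estimator is the appropriate cross-check. Measured
surfaces are those of the closed voxel solid, so when comparing a segmented
villus against the analytic capsule the base disk $\pi r^2$ is added to the
analytic lateral + cap area.

The **mesh** method extracts the half-level iso-surface of the binary
indicator by marching tetrahedra and relaxes the voxel staircase with
Taubin $\lambda/\mu$ smoothing (100 passes, $\lambda = 0.5$, $\mu = -0.53$),
which unlike plain Laplacian smoothing does not shrink the mesh: flat faces
stay flat (20×10×10 µm box within 4% of its exact 1000 µm²) and curved
staircases converge to the smooth surface (digitized r = 20 sphere within
1.5%).

**Flatness** slices each instance perpendicular to its principal axis (slab
thickness twice the maximum spacing), computes 2D covariance eigenvalues of
the voxel positions per slab, and reports the median of
$\sqrt{\lambda_1/\lambda_2}$ plus the volume-weighted mean direction of the
major cross-section axis. Instances under 10 voxels, and line-like slabs,
are flagged rather than measured.

## Crypt masking choices

Annotation interpolation is shape-based: each annotated slice becomes a
signed 2D Euclidean distance field (negative inside, clamped to the slice
diagonal so annotated-empty slices stay finite), intermediate slices
interpolate the bracketing fields linearly, slices outside the annotated
range copy the nearest field, and the mask is the $\le 0$ level set. This is
a standard, deterministic realization of sparse-slice interpolation: a disk
whose radius grows linearly between annotated slices stays a disk with
linearly interpolated radius, and enlarging any annotation can only grow the
mask. Polygon annotations are rasterized with the even-odd rule at pixel
centres. When no crypt mask exists at all, the villus base falls back to the
z = 1 boundary face, with a message — cropped stacks and floorless phantoms
stay measurable.

One practical subtlety drove the emulated-annotator behaviour in the
phantom pipeline: the PSF smears the crypt-slab top upward, so thresholding
leaves a one-voxel tissue sheet just above the slab. An annotator tracing
the crypt region on those slices draws around the bright villus
cross-sections; the pipeline emulates exactly that (the annotation on the
two slices above the slab is "everything except the villus disks", then an
annotated-empty slice terminates the region). Without it the sheet attaches
to the villi and inflates their surface estimates by over 10%.

## Statistics

Group summaries and tests are computed at two levels, villus and mouse
(per-mouse means), and both are always emitted: figure legends in this
field report villus-level n, but villi within one animal are not
independent, so the pseudo-replication hazard is surfaced rather than
silently resolved. The two-group default is Welch's *t* (the pooled test is
available via `var_equal = TRUE`); multi-group designs use one-way ANOVA
with Tukey HSD, and no correction is applied across metrics — cross-metric
multiplicity is explicitly out of scope. Effect sizes are reported as mean
differences with 95% confidence intervals.

## Numerical and degenerate-input conventions

* 26-connectivity in 3D and 8-connectivity in 2D, everywhere.
* Spacing is mandatory; there is no silent 1 µm default.
* Axis order is (z, y, x) with voxel-centre coordinates $(k\,d_z, j\,d_y,
  i\,d_x)$, 0-based.
* Quality flags (`fallback_base`, `too_small`, `no_opening`,
  `absent_label`, `undefined_ratio`, `touches_border`, ...) never abort a
  batch; degenerate instances yield flagged rows so cohort tables keep one
  row per label.
* Otsu thresholding returns the upper boundary of the optimal histogram
  bin, taking the middle of the between-class-variance plateau when the
  modes are separated by an empty gap; intensities are pre-smoothed by a
  half-voxel Gaussian before thresholding to stop read noise from
  wrinkling the mask surface (which would inflate Crofton counts).
* TIFF volumes carry their OME-XML metadata in a `<path>.companion.ome`
  sidecar; integer data round-trip losslessly, floats are stored as scaled
  32-bit samples with the scale recorded in the metadata.

## Validation summary and limitations

`scripts/acceptance.R` regenerates every headline number from scratch:
20/20 random-seed phantoms recover exactly 20 instances; median absolute
errors against analytic truth on the standard phantom are ~1% (length),
~1% (volume), ~1% (Crofton surface) and ~2.5% (mesh surface); flattened
villi recover flatness within a few percent of $a^2 = 4$; the synthetic
lactation cohort recovers its 1.5× length ratio within 5% with
Tukey-adjusted p < 0.001 and significantly higher flatness; the watershed
equals its shortest-path oracle voxel-for-voxel on random masks; ANOVA
type-I error is 5% ± 2% over 1000 null simulations; and pipeline reruns are
byte-identical.

Known limitations: branched or fused villi are out of scope (the capsule
model and the seeding loop assume one blob per finger); the Crofton
estimator underestimates large axis-aligned flat faces; tilted villi are
supported by the renderer (clipped at the base plane) but the closed-form
truth is exact only for upright villi, so validation phantoms are upright;
and the intensity model is not photorealistic — conclusions about real
stacks should rest on the operator-level guarantees, not on the phantom's
realism.
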