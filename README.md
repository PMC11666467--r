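# villimorph

3D morphometry of intestinal villi from whole-mount confocal stacks.

Whole-mount imaging of cleared small-intestinal mucosa (e.g. DAPI +
phalloidin on a confocal with a 2.15 µm z-step) shows villi as finger-like
projections rising from a crypt layer. Their length, volume and surface area
set the gut's absorptive capacity and change strongly in adaptations such as
pregnancy and lactation. `villimorph` implements the full quantification
pipeline for such stacks:

1. **Crypt masking** — sparse manual 2D crypt annotations are interpolated
   to a 3D mask by signed-distance-field interpolation; removing the crypt
   region leaves the villus foreground and defines each villus's base.
2. **Instance segmentation** — iterative erosion + Laplacian-of-Gaussian
   seeding on the distance transform creates one seed per villus; a
   marker-controlled watershed (geodesic nearest-seed regrowth with exact,
   deterministic tie-breaking) regrows the seeds over the full foreground.
3. **Morphometry** — per villus, in physical µm units on the anisotropic
   grid:
   - *length*: maximum of the geodesic distance map seeded at the villus
     base (`max` readout of a within-object distance map),
   - *volume*: voxel count × voxel volume,
   - *surface area*: Crofton 13-direction line-grid estimator with
     calibrated direction weights, plus a Taubin-smoothed
     marching-tetrahedra mesh estimator as cross-check,
   - *flatness*: median cross-section covariance axis ratio
     `sqrt(lambda_major/lambda_minor)` (a capsule with elliptical
     cross-section semi-axes `(a*r, r/a)` has flatness `a^2`),
   - plus crypt depth, villus/crypt ratio, EdU migration distance and 2D
     organoid cross-section areas.
4. **Cohort statistics** — mean ± s.e.m. summaries and group comparisons
   (two-tailed Welch *t*-tests; one-way ANOVA with Tukey HSD), always at
   both the villus and the mouse level.

Because no public stack with per-villus ground truth exists, the package
also ships a **synthetic phantom generator**: two-channel mucosa volumes
(solid tissue with a bright cortical shell, PSF blur, detector noise,
anisotropic spacing) whose villi are capsules with closed-form length
`L = L_c + r`, volume `V = pi r^2 L_c + (2/3) pi r^3` and surface
`S = P(a r, r/a) L_c + S_cap` — the analytic oracle every estimator is
validated against.

## Worked example

Generate a validated two-villus phantom, segment it, and measure it:

```r
library(villimorph)

spec <- phantom_grid_spec(n_rows = 1, n_cols = 2, pitch_y = 30, pitch_x = 30,
                          margin = 16, shaft_length = 40, radius = 10,
                          spacing = c(1, 0.5, 0.5), clearance = 2, seed = 13)
ph  <- generate_phantom(spec)
seg <- segment_villi(ph$actin, ph$crypt_mask, seeding_params(
         downsample_factors = c(2, 4, 4), sigma_schedule = c(8, 6)))
m   <- measure_villi(seg$labels, seg$base, sample_id = "demo",
                     surface_method = "both")
m[, c("label_id", "length", "volume", "surface_area_crofton",
      "surface_area_mesh", "flatness")]
```

```
 label_id length   volume surface_area_crofton surface_area_mesh flatness
        1     49 14924.00             3464.518          3604.370 1.002991
        2     49 14900.75             3465.796          3601.923 1.004391
```

The analytic truth for these villi is length 50 µm, volume 14661 µm³ and
closed surface 3456 µm² (lateral 2513 + cap 628 + base disk 314). Lengths
are measured from the first voxel layer above the crypt interface (hence
~1 µm short); volumes land within ~2% (this quick example hands the raw
crypt slab to `segment_villi`, so a thin blurred sheet above the slab is
absorbed into the villi — the full pipeline's emulated annotations remove
it); the Crofton surface is within 0.3% and the mesh estimator within 4.5%.
On the package's standard 20-villus validation phantom, measured through the
full annotation pipeline, the median absolute errors against analytic truth
are about 1% (length, volume, Crofton surface) and 2.5% (mesh surface).

Group comparisons on a two-cohort phantom experiment come from
`run_pipeline()`:

```r
run_pipeline("pipeline.yaml")   # writes morphometry.csv, summary.csv,
                                # comparisons.json, runlog.json
```

A thin command-line wrapper (`inst/cli/villimorph.R`) exposes the same
stages as `phantom`, `segment`, `measure` and `run` subcommands.

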