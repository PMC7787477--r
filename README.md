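# aoreg — volumetric motion correction for AO-OCT retinal images

Adaptive-optics OCT resolves single cone photoreceptors in the living
retina, but a volume takes 100–400 ms to raster-scan while the fixating eye
drifts (~tens of um/s), trembles (~2–3 um at ~11 ms period) and
microsaccades (tens of um in ~25 ms), and the head moves axially and rolls
(torsion). Every volume is therefore a differently warped sample of the
retina, and naive averaging erases the cone mosaic. `aoreg` is for
researchers who need to register hundreds of such volumes to each other —
and to a common motion-free frame — so they can be averaged sharply,
mosaicked to a wider field of view, or focus-stacked in depth.

## Method

Fast B-scans (depth × fast-axis images, acquired in well under a
millisecond) are treated as rigid. The pipeline estimates, coarse to fine:

1. **3D B-scan registration** to a reference volume. Sub-volumes of `2d`
   B-scans every `s` B-scans are matched by 3D phase-only correlation
   (cross-power spectrum `F(a)·F(b)*` normalized to unit magnitude,
   regularized); the valid coarse displacements are interpolated to per-
   B-scan slow-axis predictions `y'_i = i − Δy'_i`; each B-scan is then
   matched by overlap-normalized 2D cross-correlation against the `2w_y+1`
   reference B-scans around its prediction, giving pixel-level
   `(Δx_i, Δy_i, Δz_i)` with `Δy_i = i − j`. B-scans with peak coefficient
   below 0.3 or with local displacement SD above 3–5 px in a ~20 ms window
   are excluded; survivors are placed at slot `i − Δy_i` (last acquired wins
   collisions; gaps are masked and vanish under multi-volume averaging).
2. **Multi-reference global registration.** Registering everything to
   several references (at least one per video, added until ≥80% of volumes
   register), the motion of reference `R`'s B-scan `j` is estimated as
   `a_{j;R}`, the mean displacement of all target B-scans matched to it.
   Each B-scan's global position estimate through `R`,
   `p = a_{j;R} − Δd + s_i` with scanner term `s_i = (0, i−⟨i⟩, 0)`, differs
   across references by unknown per-reference constants; these are solved
   exactly by per-axis linear least squares over the reference-overlap graph
   (gauge `ε_{R0} = 0`), and averaging `p + ε̂_R` with a zero-mean
   constraint yields B-scan global coordinates `τ_{i,T}`. A per-video
   en-face similarity transform `A_T` (rotation = torsion, isotropic scale)
   then maps every A-line to its global coordinate
   `χ_{α,i,T} = A_T (τ_{i,T} + ς_α)`, `ς_α = (α−⟨α⟩, 0, 0)`.
3. **Rendering and metrics.** A-lines are splatted at `round(χ)` onto an
   auto-expanding grid with per-voxel counts (the same machinery mosaics
   displaced patches and merges focus stacks), and image quality is scored
   by cone-mosaic power-spectrum metrics: relative spectral contrast at the
   cone-spacing frequency, image sharpness ratio (ISR), MSE, and mosaic SNR
   (cone-frequency power over the high-frequency noise floor, radially or
   per scan axis).

A synthetic retina (hexagonal cone mosaic over IS/OS–RPE reflectance bands)
and a fixational eye-motion simulator generate volumes with exported ground
truth, so every stage is validated by parameter recovery. See the methods
vignette (`vignettes/aoreg-methods.Rmd`) for models, parameter meanings and
design rationale, and `FORMATS.md` for file formats.

## Worked example

Simulate a drifting, trembling eye viewing a cone mosaic, register one
volume to another, and measure the recovery:

```r
library(aoreg)

ph <- build_phantom(size = c(x = 140, y = 140, z = 110), cone_spacing = 6,
                    seed = 3)
sc <- scan_params(n_x = 96, n_z = 96, n_y = 64)
pp <- motion_params(drift_speed = 30, tremor_amplitude = 2.5,
                    microsaccade_rate = 0, seed = 11)
ds <- simulate_dataset(ph, sc, pp, volumes_per_video = 3, seed = 5)
vols <- lapply(ds$volumes, normalize_intensity)

disp <- register_bscans(vols[[2]], vols[[1]], s = 10, d = 6)
head(disp$displacements[, c("i", "j", "dx", "dy", "dz", "ncc", "included")])
#>   i j dx dy dz       ncc included
#> 1 1 1  0  0 -1 0.9256051     TRUE
#> 2 2 5 -2 -3 -1 0.9309326     TRUE
#> 3 3 7 -5 -4 -1 0.9279859     TRUE
#> 4 4 7 -6 -3 -1 0.9280643     TRUE
#> 5 5 7 -6 -2 -1 0.9305392     TRUE
#> 6 6 6 -4  0 -1 0.9254524     TRUE
```

Each row gives the displacement of target B-scan `i` relative to its
best-matching reference B-scan `j` (`dy = i - j`), the NCC peak coefficient,
and whether the B-scan survived the outlier filters: here the first B-scans
of the target were acquired while tremor had displaced the eye by a few
micrometers relative to the reference's acquisition. Placing the B-scans at
their registered slots shows the folding that fixational motion causes:

```r
reg <- construct_registered(vols[[2]], disp)
str(reg$report)
#> List of 6
#>  $ placed  : int 35
#>  $ excluded: int 0
#>  $ collided: int 29
#>  $ dropped : int 0
#>  $ gaps    : int 29
#>  $ empty   : logi FALSE
```

All 64 B-scans registered; tremor made the scanner revisit retinal rows, so
29 placements collided (the last acquired B-scan wins) and the mirror-image
29 slots are gaps — which vanish once several registered volumes are
averaged, because gaps fall at different slots in every volume. The full
cascade —
`run_pipeline()` — chains pre-processing, single- and multi-reference
registration, the global solve, the affine stage, rendering and metrics,
and writes all tables (see `FORMATS.md`). A thin command-line front-end
lives at `inst/scripts/aoreg.R`
(`simulate` / `register3d` / `metrics` / `run`).

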