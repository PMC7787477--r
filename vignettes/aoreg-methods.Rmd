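---
title: "Motion correction of AO-OCT volumes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion correction of AO-OCT volumes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aoreg)
```

## The problem

Adaptive-optics OCT resolves individual cone photoreceptors, but a volume
takes ~100-400 ms to raster-scan while the fixating eye drifts, trembles and
occasionally jumps. Each fast B-scan (a depth-by-fast-axis image acquired in
under a millisecond) is essentially motion-frozen, but successive B-scans
sample the retina at positions perturbed by the eye, so volumes are
non-rigidly distorted relative to one another and simple averaging destroys
the cone mosaic. `aoreg` estimates, per fast B-scan and ultimately per
A-line, where in the retina each piece of data actually came from, so that
hundreds of volumes can be averaged sharply.

The cascade has two stages:

1. **3D B-scan registration.** Every fast B-scan of a target volume is
   assigned a displacement `(dx, dy, dz)` relative to its best-matching
   B-scan in a reference volume, via coarse 3D phase-only correlation (POC)
   on sub-volume samples followed by fine overlap-normalized 2D
   cross-correlation (NCC) within a narrowed slow-axis search window.
2. **Global A-line registration.** Registrations against several references
   are fused into a single motion-free coordinate system: the reference's
   own motion is estimated by averaging the displacements of all B-scans
   matched to each of its B-scans, per-reference unknown offsets are solved
   by least squares over the reference-overlap graph, and inter-video
   torsion and scale are removed by an en-face similarity transform,
   yielding a global coordinate for every A-line.

## Conventions

One displacement convention is used everywhere, including the simulator's
ground truth: `Delta` is target-minus-reference, the slow-axis component is
the index difference `dy = i - j`, a registered B-scan is placed at slot
`i - dy`, and in-plane content is shifted by `-(dx, dz)`. The global position
of a B-scan estimated through reference `R` is

```
p[i,T;R] = a[j;R] - Delta[i,T;R] + s[i],    s[i] = (0, i - <i>, 0),
```

where `a[j;R]` is the mean displacement of all target B-scans matched to
reference B-scan `j` (the reference's own motion estimate) and `s` is the
explicit scanner trajectory. Subtracting the measured displacement from the
reference-motion estimate — rather than the reverse — is what makes `p` a
*content* position: with it, B-scans imaging the same retinal patch receive
the same global coordinate, which the parameter-recovery tests verify
directly against the simulator's ground truth. `p` differs across references
only by per-reference constants `eps[R]`; these are the unknowns of the
least-squares gauge solve below.

## Stage 1: coarse-to-fine B-scan registration

**Coarse.** Sub-volumes of `2d` contiguous B-scans every `s` B-scans are
registered rigidly to the reference by 3D POC (`Eq.`-style cross-power
spectrum normalized to unit magnitude, inverse transformed, peak decoded to
signed shifts in `[-dim/2, dim/2)`). Defaults `s = 15`, `d = 6` keep samples
under 30 ms apart (capturing 10-60 ms motion components) while each sample
spans ~11 ms, short enough to be motion-frozen. The reference is padded to
powers of two in (z, x) and to a multiple of `2d` in y; the target sample is
embedded at its original slow-axis location so the POC peak reads out the
displacement directly. Two robustness details matter in practice:

* *Spectral floor.* Bins of the cross-power spectrum below `1e-6` of the
  maximum magnitude are zeroed rather than normalized. Phase-only whitening
  treats every bin equally; on low-noise data most bins hold only
  floating-point round-off, and whitening them buries the true peak under
  random-phase noise.
* *Trend filter.* Samples whose slow-axis displacement jumps by more than
  `s` relative to both neighbours (one neighbour at trace ends) are
  dropped; valid samples are linearly interpolated (and extrapolated at the
  edges) to per-B-scan position predictions `y_pred = i - dy_pred`.

**Fine.** Each target B-scan is correlated against the `2*w_y + 1`
(default 17) reference B-scans around `round(y_pred)`; the global argmax
over candidates gives `(dx, dz)` (NCC peak) and `dy = i - j*`. Registration
is deliberately pixel-level; sub-pixel refinement is out of scope. The NCC
is the FFT masked/overlap-normalized form, so zero padding never biases
coefficients; offsets with less than `min_overlap` (default one half) of the
B-scan area overlapping are inadmissible, because per-B-scan eye motion
never approaches half the field while the quasi-periodic mosaic happily
produces high-coefficient false matches at large offsets. Predictions that
fall slightly (up to `2*w_y`) outside the reference are clamped to its edge
— the linear extrapolation is least reliable exactly there — while farther
predictions mark the B-scan unmatched.

**Filtering and construction.** A B-scan is excluded when its coefficient
falls below `ncc_min = 0.3` or when the standard deviation of displacements
within a ~20-ms window centered on it (converted through the B-scan rate,
at least 5 B-scans) exceeds `sigma_max_px = 4` (useful range 3-5) on any
axis. Included B-scans are placed at `i - dy` with in-plane shift
`-(dx, dz)`; when several land on one slot the last acquired wins, and
empty slots are flagged as gaps. Gaps vary randomly between volumes, so
averaging many registered volumes fills them; the averaging honours gap
masks and reports per-slot contribution counts.

## Stage 2: multi-reference global registration

A single reference cannot register volumes that are decorrelated from it
(torsion, focus change, non-overlapping patches), and everything registered
to it inherits its private distortion. The global stage therefore registers
every volume against several references (by default the best volume of each
video by the reference-quality metric `m`, adding next-best candidates until
at least 80% of volumes register), estimates each reference's own motion
`a[j;R]`, forms `p` as above, and solves

```
min over eps : sum over pairs (R, R') of
               sum over B-scans registered to both of
               ((p[.;R] + eps[R]) - (p[.;R'] + eps[R']))^2
```

independently per axis with the gauge `eps[R0] = 0`. The quadratic has an
exact minimizer — a graph-Laplacian linear system over the reference-overlap
graph — so no iterative scheme is needed; tests confirm agreement with a
brute-force numerical minimization. Disconnected overlap components are
gauged separately with a warning. Averaging `p + eps` over the references
each B-scan registered to, then removing the grand mean (the fixating eye's
displacement averages to zero by design), yields the B-scan global
coordinates `tau`. Reference B-scans get their coordinates from the same
solve, since references are registered to each other like any target.

**Torsion and scale.** Head/eye roll and magnification drift are constant
within a ~5 s video but vary between videos. One similarity transform
(rotation, isotropic scale, translation) per video is estimated by fitting
each member volume's raw en-face projection against the en-face projection
of the reference volume (the volume with the lowest variance in `tau`) and
averaging the per-volume angles and log-scales. Raw en-face projections are
used deliberately: the B-scan stage absorbs part of a video's torsion into
its per-B-scan `dx` corrections, so images rebuilt from `tau` under-report
torsion by a fraction that depends on which references each volume
registered to, whereas raw projections keep the full signature; averaging
per-volume *estimates* instead of registered *images* avoids the blur that
integer-precision placement adds (measured: registered-average subsets
shrank recovered rotation by ~15%). The optimizer is Nelder-Mead over a
masked-NCC (default) or joint-histogram mutual-information similarity with
bilinear warping, with translation initialized at the masked-NCC peak — the
mosaic is quasi-periodic, and a zero-translation start can lock onto a
lattice-aliased optimum. Two robustness guards matter: member fits whose
final similarity falls well below the best member's (lattice-aliased
optima) are excluded from the average, and the correction is applied only
when the similarity model beats translation-only alignment by a clear
margin (`gate`, default 0.002) — on torsion-free data the extra degrees of
freedom otherwise fit noise, and a spurious rotation/scale visibly degrades
the rendered average. The estimated linear block (not the translation,
which relates raw frames that `tau` has already aligned) is applied to
every A-line: `chi = A_T (tau + (alpha - <alpha>, 0, 0))`, depth passed
through unchanged.

**Rendering.** Every A-line's pixels are splatted to the nearest voxel
column at `round(chi)` with per-voxel accumulation and counts; the grid
auto-expands to the coordinate bounding box, which is what extends the field
of view when references tile displaced patches, and focus stacks merge the
same way. Rounding uses half-up (`floor(x + 0.5)`) so the half-integer
coordinates of even-sized grids map consistently.

## The simulator

The generator exists so that every stage is testable by parameter recovery;
its defaults are the study conditions, not tuning dials.

* **Phantom.** Reflectance bands emulating IS/OS, COST, ROST and RPE (axial
  Gaussians; FWHM 6-10 um) over a hexagonal cone lattice with
  nearest-neighbour spacing 6 um, positional jitter 0.8 um, and per-cone
  brightness in 0.75-1.25; non-mosaic bands carry a smooth random texture
  (correlation length half the cone spacing). Lateral patterns are
  rasterized once on a 1 um grid and interpolated bilinearly; axial profiles
  are analytic. The lattice's first spectral ring (Yellott) sits at
  `2/(sqrt(3) * spacing)`; `cone_peak_frequency()` exposes it and the
  spectral metrics take the corresponding period `sqrt(3)/2 * spacing`.
* **Motion.** Drift as a piecewise-linear random walk (default 30 um/s,
  heading persistence 0.5 s); tremor as a narrowband stochastic oscillation
  per lateral axis (2.5 um amplitude, 11 ms period, complex envelope with
  ~5-cycle coherence — physiological tremor is band-limited noise, and a
  phase-locked tone would alias against the volume rate, making every
  volume of a video skip the same slow-axis rows); Poisson-scheduled
  microsaccades (raised-cosine ramps, 30 um over 25 ms by default); an
  axial sinusoid (5 um, 1 s period); and per-video torsion (SD 0.15 deg)
  and isotropic scale (SD 0.005) held constant within a video. One
  translation sample per B-scan interval: B-scans are rigid by
  construction, as in the registration model. Multi-volume experiments
  space volumes at the acquisition protocol's 2.4 volumes/s rather than
  back to back, which decorrelates motion between volumes. All magnitudes
  are parameters; the eccentricity-dependent conversion between
  "photoreceptors traversed" and micrometers is left to the user via
  `cone_spacing` and the motion amplitudes.
* **Sampling.** B-scan `i` samples the phantom at the (optionally nonlinear
  via `scan_pattern`, optionally tilted) scanner position offset by the
  motion sample for its acquisition time, rotated/scaled about the volume
  center; multiplicative exponential (speckle-like) noise and an additive
  exponential floor follow. Ground truth is exported in pixels in the
  registration sign convention (`d = -m / pitch`).

What the simulator does not emulate — OCT speckle statistics beyond a
multiplicative exponential, depth-dependent defocus, vascular shadows,
intra-cellular reflectance dynamics — bounds what passing tests show:
recovery holds for geometrically faithful, moderately noisy data, not for
arbitrary real-world image content.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` re-derive the package's guarantees
at sizes chosen to run comfortably on one CPU:

* *Oracle equivalence.* POC against an explicit DFT-matrix implementation
  (8^3), planted integer shifts (16^3), and NCC coefficient maps against
  sliding-window Pearson correlations (32 x 32, agreement to 1e-6).
* *B-scan stage.* Ten drift+tremor volumes of 64 B-scans x 96 x 96 px;
  per-axis displacement RMSE against ground truth at most 1 px on included
  B-scans; a volume with one mid-volume 30 um microsaccade still registers,
  with errors confined to the saccade interval.
* *Global stage.* (a) Nine strongly moving volumes in three videos, no
  torsion: `tau` matches ground-truth retinal positions up to a constant
  with RMS at most 1 px per axis, and the gauge/zero-mean identities hold to
  1e-6 px. (b) A four-video torsion chain (0, 0.4, 0.7, 1.0 deg; scales 1 to
  1.02) with mild translation motion: the recovered inter-video torsion
  difference is within 0.1 deg of the imposed 1.0 deg and the scale ratio
  within 0.005 of 1.02. The chain design mirrors real datasets, where
  torsion varies continuously across many videos; imposing a full degree
  between adjacent videos would simply make them unregistrable to each
  other's references — the same failure the single-reference method shows on
  real data, and the reason the multi-reference stage exists.
* *Metric trends.* Registered averages beat unregistered averages in
  relative spectral contrast and sharpness ratio (and are lower in MSE) at
  every averaging count from 2 upward; comparisons run over the covered
  common pixel region (the sharpness ratio and MSE are defined over pixels
  common to both images, and zero-filled gaps or shift borders would
  otherwise dominate).
* *SNR ordering.* The mosaic-SNR ordering global >= single-reference >=
  unregistered is demonstrated on 2 videos x 10 noisy volumes acquired at
  2.4 volumes/s, with the single-reference arm registered to a reference of
  typical (not quality-metric-optimal) motion — the deliberately distorted
  reference — and the global arm using five references. This isolates the
  mechanism the global stage exists for: the single-reference result is
  capped by its reference's private distortion, which the multi-reference
  solve removes (measured: ~21.9 vs ~17.0 vs ~15.1 dB). Two caveats are
  worth stating plainly. With the quality-metric-optimal reference and only
  two references, the two registered averages differ by under ~1 dB at this
  problem size: the full effect needs wide fields (where torsion visibly
  blurs single-reference averages) and tens of references / hundreds of
  averaged volumes. And the unregistered leg requires laterally
  decorrelated volumes; when volumes happen to be aligned, the SNR ratio
  can reward blur, because smoothing suppresses the high-frequency tail
  faster than the cone peak.

## Numerical choices and degenerate inputs

* Argmax ties in POC/NCC break at the first occurrence in column-major
  (z, x, y) order; coefficients are clipped to `[-1, 1]` against
  floating-point excess.
* POC inputs are mean-subtracted before padding and the unit-magnitude
  normalization is regularized (`S / (|S| + 1e-4 max|S|)`): without both,
  the DC spike dominates the cross-power magnitude and, on low-noise data,
  whitened round-off bins flood the correlation surface with random phase.
  Padding is to strictly greater sizes (a dimension already at a power of
  two would otherwise receive no padding at all and the correlation would
  wrap circularly).
* En-face projections of global averages use `render_enface()`, which
  averages only covered voxels per column: the global grid's depth extent
  exceeds one volume's, and a plain z-mean would modulate the image with
  each column's covered fraction.
* NCC variance terms are guarded relative to each image's total energy
  (1e-9): an exactly constant overlap region otherwise divides round-off by
  round-off and reports coefficient 1.
* The reference-quality metric `m = mean(r) / ((sd(r) + eps) (sd(dx) + eps))`
  floors both denominators at `eps = 1e-6`; an all-constant volume is
  flagged degenerate rather than failing.
* Normalization maps `[N, M]` to `[0, 1e5]` with clamping; in automatic mode
  `N` is the 95th percentile of the top 10% of depth pixels (vitreous) and
  `M` sits 37.5 dB above it (midpoint of the 35-40 dB range that spans
  typical retinal dynamic range).
* Zero-length traces, empty volume lists, non-monotone scan patterns,
  all-zero POC inputs, all-excluded displacement sets and empty render
  requests all fail fast with named errors (or flagged results where the
  pipeline should continue).

## Known limitations

* Registration is integer-pixel; residual sub-pixel motion blurs averages
  slightly (visible as the gap between registered-average and
  single-reference spectra).
* The torsion correction assumes torsion/scale constant within a video and
  negligible shear; z scaling is passed through unchanged.
* Cross-reference fusion assumes the reference-overlap graph is connected;
  disconnected components are internally consistent but only loosely
  aligned to each other (a warning is raised).
* The affine stage relies on a static, high-contrast en-face pattern; on
  low-contrast layers the mutual-information metric or manual reference
  choice may be needed, and a non-converged fit falls back to the identity
  with a flag. At 64-px fields the torsion estimator's realization-to-
  realization variability is about 0.1-0.2 degrees (a 1 degree rotation
  moves edge content by barely half a pixel); wider fields tighten it
  roughly in proportion.
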