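# File formats

All on-disk tables use 0-based indices; displacements are in pixels, angles
in degrees, pitches in micrometers per pixel.

## Volumes

- **HDF5** (canonical): dataset `intensity`, laid out `(z, x, y)` —
  `intensity[, , i]` is fast B-scan `i` (depth × fast axis). Attributes on
  the dataset: `pitch_x`, `pitch_y`, `pitch_z` (um/px), `bscan_rate` (Hz).
  Values round-trip bit-exactly at single precision.
- **Multi-page TIFF** (interchange): one 32-bit float page per B-scan
  (page = z × x). TIFF storage is defined on [0, 1], so values are divided
  by their maximum; the scale, pitches and B-scan rate are stored in a
  `<file>.tif.json` sidecar. Without a sidecar, 1 um/px and 1100 Hz are
  assumed (with a warning).

## Motion traces

CSV columns `bscan_index`, `t_ms`, `dx_px`, `dy_px`, `dz_px`. The `d*_px`
columns are ground-truth displacements in the registration sign convention
(target-minus-reference for a motion-free reference): the content of B-scan
`i` lies at slow-axis position `i - dy_px`. Per-volume torsion (deg) and
isotropic scale go to `<file>.csv.json`.

## Displacement tables

`disp_vol<T>.csv`: `i` (target B-scan, 0-based), `dx`, `dy`, `dz` (px,
target-minus-reference; `dy = i - j` with `j` the matched reference B-scan),
`ncc` (peak coefficient), `included` (survived outlier filters), `y_pred`
(coarse-predicted reference position, 0-based).

## Global coordinates

- `tau.csv`: `T` (volume), `i` (B-scan), `x`, `y`, `z` (px, zero-mean global
  frame), `defined`.
- `chi.csv`: `T`, `i`, `alpha` (A-line), `x`, `y`, `z` (px, global frame
  after the en-face affine).
- `affines.json`: per volume, the 4×4 homogeneous matrix (row-major; depth
  row/column identity) acting on centered global `(x, y, z, 1)` coordinates.

## Scan-pattern lookup

One-column CSV of monotone increasing fast-axis positions per A-line index
(arbitrary units; normalized internally).

## Configuration

JSON or YAML with the keys of `pipeline_config()`; unknown keys are
rejected. Every pipeline run writes its resolved configuration next to its
outputs (`config.json`).
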