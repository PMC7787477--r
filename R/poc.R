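#' 3D phase-only correlation of a target sub-volume against a reference
#'
#' The reference volume is zero-padded along z and x to the next power of two
#' and along y to the next multiple of the sample width `2d`; the target
#' sub-volume (a stack of contiguous fast B-scans) is zero-padded to the same
#' size, embedded at its original y location. The cross-power spectrum
#' `F(a) * Conj(F(b))` is normalized element-wise to (regularized) unit
#' magnitude and inverse-transformed; the location of
#' the maximum, unwrapped to signed shifts in `[-dim/2, dim/2)` per axis,
#' gives the displacement of the target sub-volume relative to the
#' best-matching reference sub-volume (target-minus-reference convention).
#' Argmax ties break at the first occurrence in (z, x, y) scan order.
#'
#' @param target_sub 3D array `(z, x, 2d)` cut from the target volume.
#' @param reference the full reference volume as a 3D `(z, x, y)` array, or a
#'   pre-padded spectrum from [poc_prepare_reference()].
#' @param y_start 1-based slow-axis index of the sub-volume's first B-scan.
#' @param d sample half-width in B-scans (pad granularity `2d`).
#' @param regularization the unit-magnitude normalization is regularized as
#'   `S / (|S| + regularization * max(|S|))`: bins carrying only
#'   floating-point round-off (inevitable on low-noise data) would otherwise
#'   be whitened into random phases that flood the correlation surface.
#'   Broadband (speckle-bearing) data is unaffected; exact-zero bins map
#'   to 0.
#' @return list with `dx`, `dy`, `dz` (pixels), `peak` (POC peak height) and
#'   `valid` (FALSE when either input is all-zero).
#' @export
poc3d <- function(target_sub, reference, y_start = 1L,
                  d = dim(target_sub)[3] / 2, regularization = 1e-4) {
  ref <- if (inherits(reference, "poc_reference")) reference
         else poc_prepare_reference(reference, d)
  dims <- ref$dims
  if (all(target_sub == 0) || !ref$nonzero)
    return(list(dx = NA_real_, dy = NA_real_, dz = NA_real_,
                peak = NA_real_, valid = FALSE))
  # the mean is removed before padding: the DC spike otherwise dominates the
  # cross-power magnitude and defeats the regularized normalization
  a <- pad_embed(target_sub - mean(target_sub), dims,
                 at = c(1L, 1L, as.integer(y_start)))
  Fa <- stats::fft(a)
  S <- Fa * ref$Fb_conj
  mag <- Mod(S)
  mx <- max(mag)
  if (mx == 0)
    return(list(dx = NA_real_, dy = NA_real_, dz = NA_real_,
                peak = NA_real_, valid = FALSE))
  Rn <- S / (mag + regularization * mx)
  surf <- Re(stats::fft(Rn, inverse = TRUE)) / prod(dims)
  idx <- which.max(surf)          # column-major: first in (z, x, y) order
  loc <- arrayInd(idx, dims)
  list(dz = decode_shift(loc[1], dims[1]),
       dx = decode_shift(loc[2], dims[2]),
       dy = decode_shift(loc[3], dims[3]),
       peak = surf[idx], valid = TRUE)
}

#' Pre-pad and transform a reference volume for repeated POC calls
#'
#' @param reference 3D `(z, x, y)` array.
#' @param d sample half-width in B-scans.
#' @return a `poc_reference` object caching the padded conjugate spectrum.
#' @export
poc_prepare_reference <- function(reference, d) {
  dd <- dim(reference)
  # strictly greater sizes: the POC wraps circularly, so genuine zero
  # padding must be present on every axis to suppress boundary aliases
  dims <- c(next_pow2(dd[1] + 1L), next_pow2(dd[2] + 1L),
            next_multiple(dd[3] + 1L, 2 * d))
  b <- pad_embed(reference - mean(reference), dims)
  structure(list(dims = dims, Fb_conj = Conj(stats::fft(b)),
                 nonzero = any(reference != 0)),
            class = "poc_reference")
}
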