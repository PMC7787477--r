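# Overlap-normalized (masked) 2D cross-correlation, FFT formulation.
#
# For two equal-size B-scans f (target) and t (reference), computes the
# Pearson correlation coefficient restricted to the overlapping region at
# every integer offset (u_z, u_x), so zero padding does not bias the
# coefficient. Offsets follow the target-minus-reference convention:
# the map peaks at u when f(n) ~ t(n - u).

# Precompute per-image spectra/sums shared across pairings. `geom` comes
# from ncc_geometry() and fixes the padded FFT size.
ncc_geometry <- function(nz, nx, min_overlap = 0.5) {
  P1 <- next_fast_size(2L * nz - 1L)
  P2 <- next_fast_size(2L * nx - 1L)
  mask <- matrix(0, P1, P2); mask[1:nz, 1:nx] <- 1
  Fm <- stats::fft(mask)
  n_ov <- Re(stats::fft(Fm * Conj(Fm), inverse = TRUE)) / (P1 * P2)
  n_ov <- round(n_ov)
  keep <- n_ov >= max(16, min_overlap * nz * nx)
  list(nz = nz, nx = nx, P = c(P1, P2), Fm = Fm, n_ov = n_ov, keep = keep)
}

# Target-side ("f") precomputation: F(f), running sums of f and f^2 over the
# overlap window at every offset.
ncc_prep_f <- function(f, geom) {
  P <- geom$P
  fp <- matrix(0, P[1], P[2]); fp[1:geom$nz, 1:geom$nx] <- f
  Ff <- stats::fft(fp)
  Ff2 <- stats::fft(fp^2)
  cFm <- Conj(geom$Fm)
  list(Ff = Ff,
       f_sum = Re(stats::fft(Ff * cFm, inverse = TRUE)) / prod(P),
       f2_sum = Re(stats::fft(Ff2 * cFm, inverse = TRUE)) / prod(P))
}

# Reference-side ("t") precomputation.
ncc_prep_t <- function(t_img, geom) {
  P <- geom$P
  tp <- matrix(0, P[1], P[2]); tp[1:geom$nz, 1:geom$nx] <- t_img
  Ft <- stats::fft(tp)
  Ft2 <- stats::fft(tp^2)
  list(cFt = Conj(Ft),
       t_sum = Re(stats::fft(geom$Fm * Conj(Ft), inverse = TRUE)) / prod(P),
       t2_sum = Re(stats::fft(geom$Fm * Conj(Ft2), inverse = TRUE)) / prod(P))
}

# Full masked-NCC coefficient map for a prepared (f, t) pair. The variance
# terms are guarded relative to each image's total energy: a (near-)constant
# overlap region otherwise leaves pure FFT round-off in the denominator and
# produces spurious coefficients of 1.
ncc_map <- function(pf, pt, geom, rel_eps = 1e-9) {
  P <- geom$P
  cc <- Re(stats::fft(pf$Ff * pt$cFt, inverse = TRUE)) / prod(P)
  n_ov <- geom$n_ov
  num <- cc - pf$f_sum * pt$t_sum / pmax(n_ov, 1)
  df <- pf$f2_sum - pf$f_sum^2 / pmax(n_ov, 1)
  dt <- pt$t2_sum - pt$t_sum^2 / pmax(n_ov, 1)
  tol_f <- max(rel_eps * pf$f2_sum[1, 1], 1e-300)
  tol_t <- max(rel_eps * pt$t2_sum[1, 1], 1e-300)
  ncc <- matrix(0, P[1], P[2])
  ok <- geom$keep & df > tol_f & dt > tol_t
  ncc[ok] <- num[ok] / sqrt(df[ok] * dt[ok])
  ncc[ncc > 1] <- 1; ncc[ncc < -1] <- -1
  ncc
}

# Peak of a masked-NCC map, decoded to signed (dz, dx) shifts; ties break at
# the first occurrence in (z, x) column-major order.
ncc_peak <- function(map, geom) {
  idx <- which.max(map)
  loc <- arrayInd(idx, geom$P)
  list(dz = decode_shift(loc[1], geom$P[1]),
       dx = decode_shift(loc[2], geom$P[2]),
       rho = map[idx])
}

#' Overlap-normalized cross-correlation of two equal-size B-scans
#'
#' Exposed convenience around the FFT masked-NCC core: returns the peak
#' offset (target-minus-reference) and coefficient, plus the full map.
#'
#' @param f target image (z-by-x matrix).
#' @param t_img reference image of the same size.
#' @param min_overlap minimum overlap fraction of the full image area for an
#'   offset to be considered.
#' @return list with `dz`, `dx`, `rho`, and `map`.
#' @export
ncc2d <- function(f, t_img, min_overlap = 0.5) {
  stopifnot(all(dim(f) == dim(t_img)))
  geom <- ncc_geometry(nrow(f), ncol(f), min_overlap)
  map <- ncc_map(ncc_prep_f(f, geom), ncc_prep_t(t_img, geom), geom)
  pk <- ncc_peak(map, geom)
  c(pk, list(map = map))
}
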