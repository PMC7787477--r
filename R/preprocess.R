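#' Resample A-lines to uniform fast-axis spacing and remove tilt
#'
#' Undoes the nonlinear fast-scanner motion ("de-sinusoiding"): every (z, y)
#' row is resampled from the measured monotone scan-pattern positions onto a
#' uniform grid by 1D linear interpolation. Optionally each B-scan is sheared
#' in z to remove the linear tilt introduced by pupil misalignment; with
#' `tilt = "auto"` the tilt slope is estimated per volume by regressing the
#' axial centroid of the brightest depth layer on x.
#'
#' @param volume an [ao_volume()].
#' @param scan_pattern `NULL` (uniform, no resampling) or a strictly monotone
#'   vector of length `n_x` of fast-axis positions (any units).
#' @param tilt `0` (none), a slope in z pixels per x pixel, or `"auto"`.
#' @return the rectified [ao_volume()].
#' @export
rectify_fast_axis <- function(volume, scan_pattern = NULL, tilt = 0) {
  stopifnot(inherits(volume, "ao_volume"))
  arr <- volume$intensity
  d <- dim(arr)
  n_z <- d[1]; n_x <- d[2]; n_y <- d[3]

  if (!is.null(scan_pattern)) {
    if (length(scan_pattern) != n_x || any(diff(scan_pattern) <= 0))
      stopf("scan_pattern must be strictly monotone of length n_x = %d", n_x)
    pos <- (scan_pattern - scan_pattern[1]) /
      (scan_pattern[n_x] - scan_pattern[1]) * (n_x - 1)
    uni <- seq(0, n_x - 1)
    if (max(abs(pos - uni)) > 1e-9) {
      for (i in seq_len(n_y)) {
        bs <- arr[, , i]
        # rows are depth z; interpolate each depth row along x
        arr[, , i] <- t(apply(bs, 1, function(row)
          stats::approx(pos, row, uni, rule = 2)$y))
      }
    }
  }

  slope <- if (identical(tilt, "auto")) estimate_tilt(arr) else as.numeric(tilt)
  if (abs(slope) > 1e-12) {
    x_c <- (n_x + 1) / 2
    zs <- seq_len(n_z)
    for (i in seq_len(n_y)) {
      bs <- arr[, , i]
      out <- bs
      for (xcol in seq_len(n_x)) {
        dz <- slope * (xcol - x_c)
        out[, xcol] <- stats::approx(zs, bs[, xcol], zs + dz, rule = 2)$y
      }
      arr[, , i] <- out
    }
  }

  volume$intensity <- arr
  volume
}

# Tilt slope (z px per x px) from the axial centroid of the brightest layer,
# regressed on x over the mean B-scan.
estimate_tilt <- function(arr) {
  mb <- apply(arr, c(1, 2), mean)  # z x x mean B-scan
  n_z <- nrow(mb); n_x <- ncol(mb)
  peak_z <- which.max(rowMeans(mb))
  win <- max(3L, round(n_z * 0.08))
  zs <- max(1L, peak_z - win):min(n_z, peak_z + win)
  w <- mb[zs, , drop = FALSE]
  w <- sweep(w, 2, apply(w, 2, min))
  tot <- colSums(w)
  ok <- tot > 0
  cent <- rep(NA_real_, n_x)
  cent[ok] <- colSums(w[, ok, drop = FALSE] * zs) / tot[ok]
  xs <- seq_len(n_x)
  stats::coef(stats::lm(cent ~ xs))[["xs"]]
}

#' Normalize volume intensities for registration
#'
#' Clamped linear rescaling: values at or above the saturation level `M` map
#' to `scale` (1e5), values below the noise offset `N` map to 0, and the range
#' in between maps linearly. With `params = "auto"`, `N` is the 95th
#' percentile of the vitreous (the top `vitreous_fraction` of depth pixels,
#' which contains no reflective structure) and `M` is set `m_db_above_n`
#' decibels above `N`.
#'
#' @param volume an [ao_volume()].
#' @param params `"auto"` or a list with elements `N` and `M` (`M > N`).
#' @param vitreous_fraction fraction of shallow depth pixels treated as
#'   vitreous for the automatic noise estimate.
#' @param m_db_above_n dynamic range (dB, power convention) between `N` and
#'   `M` in automatic mode.
#' @param scale output full-scale constant.
#' @return the normalized [ao_volume()] (values in `[0, scale]`, stored at
#'   single precision).
#' @export
normalize_intensity <- function(volume, params = "auto",
                                vitreous_fraction = 0.1,
                                m_db_above_n = 37.5, scale = 1e5) {
  stopifnot(inherits(volume, "ao_volume"))
  arr <- volume$intensity
  if (identical(params, "auto")) {
    n_z <- dim(arr)[1]
    top <- max(1L, floor(n_z * vitreous_fraction))
    N <- stats::quantile(arr[seq_len(top), , ], 0.95, names = FALSE)
    if (N <= 0) N <- max(arr) * 1e-6
    M <- N * 10^(m_db_above_n / 10)
  } else {
    N <- params$N; M <- params$M
  }
  if (is.null(N) || is.null(M) || M <= N)
    stopf("normalization requires M > N (got N = %g, M = %g)", N, M)
  out <- (arr - N) / (M - N) * scale
  out[arr < N] <- 0
  out[arr >= M] <- scale
  # single precision storage grade
  volume$intensity <- array(as.numeric(as.single(out)), dim = dim(arr))
  volume$norm <- list(N = N, M = M, scale = scale)
  volume
}

#' Reference-quality metric of a volume
#'
#' Computes the en-face projection (mean over z), then for every pair of
#' adjacent fast-B-scan lines the peak 1D normalized cross-correlation `r`
#' and its lateral offset `dx` (searched within `max_shift` pixels). Eye
#' motion shears the en-face image (systematic `dx` variation, lower `r`);
#' noise lowers `r` and scatters `dx`. The score is
#' `m = mean(r) / ((sd(r) + eps) * (sd(dx) + eps))`, larger is better.
#'
#' @param volume an [ao_volume()] with at least 3 B-scans.
#' @param max_shift lateral search half-width in pixels.
#' @param eps denominator floor guarding degenerate (zero-variance) volumes.
#' @return a list of class `reference_score` with `m`, `r_bar`, `sigma_r`,
#'   `sigma_dx` and a `degenerate` flag.
#' @export
reference_quality_metric <- function(volume, max_shift = 16, eps = 1e-6) {
  stopifnot(inherits(volume, "ao_volume"))
  ef <- t(apply(volume$intensity, c(2, 3), mean))  # y rows, x cols
  n_y <- nrow(ef)
  if (n_y < 3) stopf("reference metric needs >= 3 B-scans")
  r <- numeric(n_y - 1); dx <- numeric(n_y - 1)
  for (i in seq_len(n_y - 1)) {
    pk <- line_ncc_peak(ef[i, ], ef[i + 1, ], max_shift)
    r[i] <- pk$r; dx[i] <- pk$dx
  }
  sr <- stats::sd(r); sdx <- stats::sd(dx)
  degenerate <- sr < eps || sdx < eps
  m <- mean(r) / ((sr + eps) * (sdx + eps))
  structure(list(m = m, r_bar = mean(r), sigma_r = sr, sigma_dx = sdx,
                 degenerate = degenerate),
            class = "reference_score")
}

# Peak normalized cross-correlation between two 1D lines over integer lags
# within +/- max_shift (full-length overlap-aware Pearson correlation).
line_ncc_peak <- function(a, b, max_shift) {
  n <- length(a)
  lags <- -max_shift:max_shift
  lags <- lags[order(abs(lags), lags)]  # ties prefer the smallest shift
  best_r <- -Inf; best_dx <- 0L
  for (lag in lags) {
    ia <- max(1L, 1L + lag):min(n, n + lag)
    ib <- ia - lag
    if (length(ia) < 8) next
    va <- a[ia]; vb <- b[ib]
    sa <- stats::sd(va); sb <- stats::sd(vb)
    r <- if (sa == 0 || sb == 0) {
      if (sa == 0 && sb == 0) 1 else 0
    } else stats::cor(va, vb)
    if (r > best_r) { best_r <- r; best_dx <- lag }
  }
  list(r = best_r, dx = best_dx)
}

#' Select the reference volume
#'
#' Returns the index of the volume with the largest reference-quality score
#' `m`; ties break to the lowest index.
#'
#' @param volumes a non-empty list of [ao_volume()] objects.
#' @param scores optional pre-computed numeric vector of `m` scores.
#' @return integer index into `volumes`.
#' @export
select_reference <- function(volumes, scores = NULL) {
  if (length(volumes) == 0) stopf("select_reference: no volumes supplied")
  if (is.null(scores))
    scores <- vapply(volumes, function(v) reference_quality_metric(v)$m,
                     numeric(1))
  which.max(scores)  # which.max breaks ties at the first maximum
}

#' Crop a batch of volumes to a common B-scan size
#'
#' All volumes are center-cropped in (z, x) to the element-wise minimum shape
#' across the batch, clamped to `max_bscan` (the largest B-scan the
#' registration stages accept). The y extent is untouched.
#'
#' @param volumes list of [ao_volume()] objects.
#' @param max_bscan cap `c(z, x)` in pixels.
#' @return list of volumes with equal (z, x) shapes.
#' @export
crop_batch <- function(volumes, max_bscan = c(512, 512)) {
  if (length(volumes) == 0) return(volumes)
  shapes <- vapply(volumes, function(v) dim(v$intensity)[1:2], integer(2))
  tgt <- pmin(apply(shapes, 1, min), max_bscan)
  lapply(volumes, function(v) {
    d <- dim(v$intensity)
    z0 <- (d[1] - tgt[1]) %/% 2
    x0 <- (d[2] - tgt[2]) %/% 2
    v$intensity <- v$intensity[z0 + seq_len(tgt[1]), x0 + seq_len(tgt[2]), ,
                               drop = FALSE]
    v
  })
}
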