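#' En-face projection of a volume
#'
#' Mean over a depth band per (x, y) position.
#'
#' @param volume an [ao_volume()].
#' @param z_band integer depth indices to average over (default: full depth).
#' @return a matrix (rows = x, cols = y) of class `enface_image` with the
#'   lateral pixel pitch attached.
#' @export
enface_projection <- function(volume, z_band = NULL) {
  stopifnot(inherits(volume, "ao_volume"))
  n_z <- dim(volume$intensity)[1]
  if (is.null(z_band)) z_band <- seq_len(n_z)
  if (!length(z_band) || any(z_band < 1) || any(z_band > n_z))
    stopf("z_band must be a non-empty subset of 1..%d", n_z)
  img <- apply(volume$intensity[z_band, , , drop = FALSE], c(2, 3), mean)
  structure(img, pitch = unname(volume$pitch[c("x", "y")]),
            class = c("enface_image", "matrix", "array"))
}

#' Circumferentially averaged power spectrum of an en-face image
#'
#' The image is mean-subtracted, Hann-windowed and Fourier transformed; the
#' squared magnitude is averaged over annuli of one frequency-bin width
#' (bin = 1 / (min extent)). The DC bin is excluded.
#'
#' @param image matrix (an `enface_image` or plain matrix, >= 16 x 16).
#' @param pitch lateral pixel pitch in um/px (scalar or `c(x, y)`); taken
#'   from the image attribute when present.
#' @return data.frame with `freq` (annulus centers, cycles/um) and `power`.
#' @export
radial_power_profile <- function(image, pitch = NULL) {
  img <- unclass(image)
  if (is.null(pitch)) pitch <- attr(image, "pitch")
  if (is.null(pitch)) pitch <- c(1, 1)
  pitch <- rep_len(as.numeric(pitch), 2)
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 16 || nc < 16) stopf("image must be at least 16 x 16")

  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(nr), hann(nc))
  P <- Mod(stats::fft((img - mean(img)) * w))^2

  fr <- fft_freqs(nr, pitch[1])
  fc <- fft_freqs(nc, pitch[2])
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  bin <- 1 / (min(nr * pitch[1], nc * pitch[2]))
  k <- round(rad / bin)
  k[k < 1] <- 1L
  k[1, 1] <- 0L  # DC excluded
  kmax <- floor(min(max(abs(fr)), max(abs(fc))) / bin)
  sel <- k >= 1L & k <= kmax
  pow <- tapply(P[sel], k[sel], mean)
  data.frame(freq = as.integer(names(pow)) * bin, power = as.numeric(pow))
}

fft_freqs <- function(n, pitch) {
  c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * pitch)
}

# Power at a one-annulus band centered on frequency f0.
profile_power_at <- function(profile, f0, band_bins = 1) {
  bin <- profile$freq[2] - profile$freq[1]
  sel <- abs(profile$freq - f0) <= band_bins * bin / 2 + 1e-12
  if (!any(sel)) stopf("frequency %.4g is outside the profile range", f0)
  mean(profile$power[sel])
}

#' Relative power spectral contrast between two images
#'
#' `10 log10` of the ratio of the two radial power spectra sampled at the
#' cone-spacing frequency `1 / cone_period`. Positive values mean the first
#' image carries more mosaic power; antisymmetric in its arguments.
#'
#' @param avg,ref en-face images of matching extents.
#' @param cone_period dominant mosaic period in um (for a hexagonal mosaic
#'   with nearest-neighbour spacing a, the period is `sqrt(3)/2 * a`; see
#'   [cone_peak_frequency()]).
#' @param band_bins width of the sampling band in profile bins.
#' @return contrast in dB (power convention).
#' @export
relative_spectral_contrast <- function(avg, ref, cone_period,
                                       band_bins = 1) {
  stopifnot(all(dim(avg) == dim(ref)))
  f0 <- 1 / cone_period
  pa <- profile_power_at(radial_power_profile(avg), f0, band_bins)
  pr <- profile_power_at(radial_power_profile(ref), f0, band_bins)
  if (pr <= 0) stopf("reference image has no power at the cone frequency")
  10 * log10(pa / pr)
}

#' Image sharpness ratio (ISR)
#'
#' Ratio of summed spatial-gradient magnitudes of the averaged image to the
#' reference image over their common pixels; central differences inside,
#' one-sided at the borders. Values below 1 indicate sharpness lost to
#' residual misregistration during averaging.
#'
#' @param avg,ref en-face images of matching extents.
#' @return the (unclamped) sharpness ratio.
#' @export
isr <- function(avg, ref) {
  stopifnot(all(dim(avg) == dim(ref)))
  den <- sum(gradient_magnitude(unclass(ref)))
  if (den == 0) stopf("reference image has zero gradient energy")
  sum(gradient_magnitude(unclass(avg))) / den
}

gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img; gy <- img
  gx[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[1, ] <- img[2, ] - img[1, ]; gx[nr, ] <- img[nr, ] - img[nr - 1, ]
  gy[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[, 1] <- img[, 2] - img[, 1]; gy[, nc] <- img[, nc] - img[, nc - 1]
  sqrt(gx^2 + gy^2)
}

#' Mean squared error between two en-face images
#'
#' @param avg,ref en-face images of matching extents.
#' @return mean of squared pixel differences.
#' @export
mse <- function(avg, ref) {
  stopifnot(all(dim(avg) == dim(ref)))
  mean((unclass(avg) - unclass(ref))^2)
}

#' Cone-mosaic spectral signal-to-noise ratio
#'
#' `10 log10` of the ratio of radial-profile power at the cone-spacing
#' frequency to the noise floor, estimated as the median power over the
#' high-frequency tail (`noise_band`, default the top 20% of radial
#' frequencies). With `axis = "fast"` or `"slow"` the spectrum is computed
#' per 1D line along that axis and averaged across lines, which isolates
#' sampling irregularity introduced along the slow scan axis.
#'
#' @param image an en-face image (rows = x fast axis, cols = y slow axis).
#' @param cone_period dominant mosaic period, um.
#' @param noise_band fraction `c(lo, hi)` of the maximum frequency treated
#'   as noise tail.
#' @param axis `"radial"` (2D profile), `"fast"` or `"slow"`.
#' @param pitch pixel pitch um/px (from the image attribute when absent).
#' @return SNR in dB.
#' @export
mosaic_snr <- function(image, cone_period, noise_band = c(0.8, 1),
                       axis = c("radial", "fast", "slow"), pitch = NULL) {
  axis <- match.arg(axis)
  if (is.null(pitch)) pitch <- attr(image, "pitch")
  if (is.null(pitch)) pitch <- c(1, 1)
  pitch <- rep_len(as.numeric(pitch), 2)
  f0 <- 1 / cone_period
  if (axis == "radial") {
    prof <- radial_power_profile(image, pitch)
  } else {
    img <- unclass(image)
    if (axis == "slow") { img <- t(img); pitch <- rev(pitch) }
    # spectrum along rows' second dimension? rows = lines along the axis
    n <- nrow(img)
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    P <- 0
    for (cidx in seq_len(ncol(img))) {
      line <- img[, cidx]
      P <- P + Mod(stats::fft((line - mean(line)) * hann))^2
    }
    P <- P / ncol(img)
    fr <- fft_freqs(n, pitch[1])
    pos <- fr > 0
    prof <- data.frame(freq = fr[pos], power = P[pos])
    prof <- prof[order(prof$freq), ]
  }
  fmax <- max(prof$freq)
  if (noise_band[1] * fmax <= f0)
    stopf("noise band must lie strictly above the cone frequency")
  nsel <- prof$freq >= noise_band[1] * fmax & prof$freq <= noise_band[2] * fmax
  if (!any(nsel)) stopf("empty noise band")
  floor_p <- stats::median(prof$power[nsel])
  sig <- profile_power_at(prof, f0)
  10 * log10(sig / floor_p)
}

#' Convert a power-ratio improvement in dB to a percent increase
#'
#' `100 * (10^(dB/10) - 1)`; e.g. 1.37 dB is a 37% increase and 9.4 dB a
#' 771% increase.
#'
#' @param db power-ratio decibels.
#' @param round_to_integer round to the nearest whole percent.
#' @return percent increase.
#' @export
db_percent <- function(db, round_to_integer = TRUE) {
  p <- 100 * (10^(db / 10) - 1)
  if (round_to_integer) round(p) else p
}
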