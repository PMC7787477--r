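#' Raster scan parameters
#'
#' @param n_x A-lines per fast B-scan.
#' @param n_z depth pixels per A-line.
#' @param n_y fast B-scans per volume.
#' @param bscan_rate B-scan rate, Hz.
#' @param pitch pixel pitch `c(x=, y=, z=)`, um/px.
#' @param scan_pattern `NULL` for uniform sampling, or a monotone increasing
#'   numeric vector of length `n_x` of unit-normalized fast-axis positions
#'   (0 = first, 1 = last A-line position).
#' @param volume_rate volume acquisition rate, Hz; defaults to back-to-back
#'   volumes (`bscan_rate / n_y`).
#' @param tilt_slope image-space tilt of the retina: z pixels of ramp per x
#'   pixel across the fast axis (models pupil-displacement time-of-flight
#'   tilt; 0 = none).
#' @param z0 depth (um) of the first sampled pixel.
#' @return a list of class `scan_params`.
#' @export
scan_params <- function(n_x = 96, n_z = 96, n_y = 64, bscan_rate = 1100,
                        pitch = c(x = 1, y = 1, z = 1), scan_pattern = NULL,
                        volume_rate = bscan_rate / n_y, tilt_slope = 0,
                        z0 = 0) {
  if (n_x <= 0 || n_y <= 0 || n_z <= 0) stopf("n_x, n_y, n_z must be > 0")
  if (bscan_rate <= 0) stopf("bscan_rate must be > 0")
  if (!is.null(scan_pattern)) {
    if (length(scan_pattern) != n_x || any(diff(scan_pattern) <= 0))
      stopf("scan_pattern must be a strictly increasing vector of length n_x")
  }
  structure(list(n_x = as.integer(n_x), n_z = as.integer(n_z),
                 n_y = as.integer(n_y), bscan_rate = bscan_rate,
                 pitch = pitch[c("x", "y", "z")], scan_pattern = scan_pattern,
                 volume_rate = volume_rate, tilt_slope = tilt_slope, z0 = z0),
            class = "scan_params")
}

#' Sample one distorted AO-OCT volume from a phantom
#'
#' B-scan `i` of volume `volume_index` samples the phantom at the scanner
#' position offset by the motion-trace sample for that B-scan interval (all
#' A-lines of a B-scan share one motion sample: B-scans are rigid), with the
#' lateral sampling grid rotated by the volume's torsion angle about the
#' volume center and scaled isotropically. Multiplicative exponential
#' (speckle-like) noise and an additive exponential floor are applied.
#'
#' Ground truth per B-scan is returned in pixels in the registration sign
#' convention (`d = -m / pitch`), so that for a motion-free reference the
#' estimated `(dx, dy, dz)` of the B-scan equals the truth and its content
#' position along y is `i - dy`.
#'
#' @param phantom an [build_phantom()] result.
#' @param trace a [simulate_motion()] trace covering the volume's span.
#' @param scan a [scan_params()] object.
#' @param volume_index 1-based index of the volume within the trace.
#' @param noise_sd multiplicative noise fraction (0 = none).
#' @param noise_floor additive floor as a fraction of the mean bright-layer
#'   signal.
#' @param video optional video index stored in the volume id.
#' @param seed integer seed for the noise realization.
#' @return `list(volume = ao_volume, truth = data.frame, torsion_deg, scale)`.
#' @export
acquire_volume <- function(phantom, trace, scan, volume_index = 1,
                           noise_sd = 0.2, noise_floor = 0.01,
                           video = 1, seed = NULL) {
  stopifnot(inherits(phantom, "ao_phantom"), inherits(trace, "motion_trace"),
            inherits(scan, "scan_params"))
  n_x <- scan$n_x; n_y <- scan$n_y; n_z <- scan$n_z
  px <- scan$pitch[["x"]]; py <- scan$pitch[["y"]]; pz <- scan$pitch[["z"]]

  t0 <- (volume_index - 1) / scan$volume_rate
  t_bscan <- t0 + (seq_len(n_y) - 1L) / scan$bscan_rate
  k <- round(t_bscan * trace$bscan_rate) + 1L
  if (max(k) > length(trace$t_ms))
    stopf("motion trace (%.3f s) does not cover volume %d (needs %.3f s)",
          max(trace$t_ms) / 1000, volume_index, max(t_bscan))
  if (volume_index > length(trace$torsion_deg))
    stopf("trace has no torsion/scale sample for volume %d", volume_index)

  # Fast-axis scanner positions (um), possibly uneven.
  frac <- if (is.null(scan$scan_pattern)) {
    if (n_x > 1) (seq_len(n_x) - 1) / (n_x - 1) else 0
  } else {
    sp <- scan$scan_pattern
    (sp - sp[1]) / (sp[n_x] - sp[1])
  }
  sx <- frac * (n_x - 1) * px
  cx <- (n_x - 1) / 2 * px
  cy <- (n_y - 1) / 2 * py
  zg <- scan$z0 + (seq_len(n_z) - 1) * pz

  theta <- trace$torsion_deg[volume_index] * pi / 180
  sf <- trace$scale[volume_index]
  ct <- cos(theta); st <- sin(theta)

  arr <- array(0, dim = c(n_z, n_x, n_y))
  lay <- phantom$layers
  for (i in seq_len(n_y)) {
    ki <- k[i]
    ux <- sx - cx
    uy <- (i - 1) * py - cy
    X <- cx + sf * (ct * ux - st * uy) + trace$mx_um[ki]
    Y <- cy + sf * (st * ux + ct * uy) + trace$my_um[ki]
    zoff <- trace$mz_um[ki] + scan$tilt_slope * (sx - cx) / px * pz
    # separable evaluation: per-layer lateral value x axial band profile
    bs <- matrix(phantom$background, n_z, n_x)
    mos <- NULL; tex <- NULL
    for (l in seq_len(nrow(lay))) {
      if (lay$mosaic[l]) {
        if (is.null(mos))
          mos <- interp_lateral(phantom$mosaic, phantom$gx0, phantom$gy0,
                                phantom$grid_pitch, X, Y)
        latv <- mos
      } else {
        if (is.null(tex))
          tex <- interp_lateral(phantom$texture, phantom$gx0, phantom$gy0,
                                phantom$grid_pitch, X, Y)
        latv <- tex
      }
      ax <- axial_profile(outer(zg, zoff, "+"), lay$depth[l], lay$thickness[l])
      bs <- bs + lay$brightness[l] * ax * rep(latv, each = n_z)
    }
    arr[, , i] <- bs
  }

  if (noise_sd > 0 || noise_floor > 0) {
    arr <- with_seed(seed, {
      n_vox <- length(arr)
      if (noise_sd > 0)
        arr <- arr * pmax(0, 1 + noise_sd * (stats::rexp(n_vox) - 1))
      if (noise_floor > 0) {
        lev <- noise_floor * max(lay$brightness)
        arr <- arr + lev * stats::rexp(n_vox)
      }
      arr
    })
  }

  truth <- data.frame(
    i = seq_len(n_y),
    t_ms = t_bscan * 1000,
    dx_px = trace$dx_px[k], dy_px = trace$dy_px[k], dz_px = trace$dz_px[k])

  list(volume = ao_volume(arr, pitch = scan$pitch,
                          bscan_rate = scan$bscan_rate,
                          id = list(video = video, volume = volume_index)),
       truth = truth,
       torsion_deg = trace$torsion_deg[volume_index],
       scale = sf)
}

#' Simulate a multi-video AO-OCT dataset with ground truth
#'
#' Convenience wrapper: one motion trace per video (independent seeds derived
#' from `seed`), `volumes_per_video` volumes acquired per trace.
#'
#' @param phantom an [build_phantom()] result.
#' @param scan a [scan_params()] object.
#' @param params a [motion_params()] object; its seed is re-derived per video.
#' @param n_videos,volumes_per_video dataset layout.
#' @param noise_sd,noise_floor noise settings passed to [acquire_volume()].
#' @param seed master seed.
#' @return list with `volumes` (list of `ao_volume`), `truth` (data.frame with
#'   video/volume columns), `traces` (per-video motion traces), and `video`
#'   (integer vector mapping volumes to videos).
#' @export
simulate_dataset <- function(phantom, scan, params = motion_params(),
                             n_videos = 1, volumes_per_video = 4,
                             noise_sd = 0.2, noise_floor = 0.01, seed = 1) {
  volumes <- list(); truth <- list(); traces <- list(); video_of <- integer(0)
  duration <- volumes_per_video / scan$volume_rate + 2 / scan$bscan_rate
  for (v in seq_len(n_videos)) {
    p <- params
    p$seed <- seed * 1000L + v
    tr <- simulate_motion(duration, p, bscan_rate = scan$bscan_rate,
                          n_volumes = volumes_per_video, pitch = scan$pitch)
    traces[[v]] <- tr
    for (w in seq_len(volumes_per_video)) {
      acq <- acquire_volume(phantom, tr, scan, volume_index = w,
                            noise_sd = noise_sd, noise_floor = noise_floor,
                            video = v, seed = seed * 10000L + v * 100L + w)
      volumes[[length(volumes) + 1L]] <- acq$volume
      tt <- acq$truth
      tt$video <- v; tt$volume <- length(volumes)
      tt$torsion_deg <- acq$torsion_deg; tt$scale <- acq$scale
      truth[[length(truth) + 1L]] <- tt
      video_of <- c(video_of, v)
    }
  }
  list(volumes = volumes, truth = do.call(rbind, truth), traces = traces,
       video = video_of)
}
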