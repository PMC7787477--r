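#' Fixational eye/head motion parameters
#'
#' Magnitudes follow the classical description of fixational eye movements:
#' slow drift wandering over ~1 s intervals, tremor of ~2-3 um amplitude with
#' ~11 ms period, abrupt microsaccades completing in ~25 ms, slow axial head
#' ripple with ~1 s period, inter-video torsion with ~0.15 deg SD and small
#' isotropic scale changes.
#'
#' @param drift_speed drift speed, um/s.
#' @param tremor_amplitude tremor amplitude per lateral axis, um.
#' @param tremor_period tremor period, ms.
#' @param microsaccade_rate Poisson rate of microsaccades, events/s.
#' @param microsaccade_amplitude total displacement of one microsaccade, um.
#' @param microsaccade_duration duration of the displacement ramp, ms.
#' @param axial_amplitude axial ripple amplitude, um.
#' @param axial_period axial ripple period, s.
#' @param torsion_sd SD of the per-volume torsion angle, deg.
#' @param scale_sd SD of the per-volume isotropic scale about 1.
#' @param seed integer; fixes the full motion realization.
#' @return a list of class `motion_params`.
#' @export
motion_params <- function(drift_speed = 30,
                          tremor_amplitude = 2.5,
                          tremor_period = 11,
                          microsaccade_rate = 0.5,
                          microsaccade_amplitude = 30,
                          microsaccade_duration = 25,
                          axial_amplitude = 5,
                          axial_period = 1,
                          torsion_sd = 0.15,
                          scale_sd = 0.005,
                          seed = 1) {
  p <- list(drift_speed = drift_speed, tremor_amplitude = tremor_amplitude,
            tremor_period = tremor_period,
            microsaccade_rate = microsaccade_rate,
            microsaccade_amplitude = microsaccade_amplitude,
            microsaccade_duration = microsaccade_duration,
            axial_amplitude = axial_amplitude, axial_period = axial_period,
            torsion_sd = torsion_sd, scale_sd = scale_sd, seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (any(unlist(num) < 0)) stopf("motion amplitudes/rates must be >= 0")
  class(p) <- "motion_params"
  p
}

#' Preset motion parameter sets
#'
#' `"none"` freezes the eye; `"drift"`, `"tremor"` and `"microsaccade"`
#' isolate one movement component; `"full"` combines all of them at their
#' default magnitudes.
#'
#' @param preset one of `"none"`, `"drift"`, `"tremor"`, `"microsaccade"`,
#'   `"full"`.
#' @param seed integer seed passed through to [motion_params()].
#' @return a `motion_params` object.
#' @export
motion_preset <- function(preset = c("full", "none", "drift", "tremor",
                                     "microsaccade"),
                          seed = 1) {
  preset <- match.arg(preset)
  zero <- motion_params(drift_speed = 0, tremor_amplitude = 0,
                        microsaccade_rate = 0, axial_amplitude = 0,
                        torsion_sd = 0, scale_sd = 0, seed = seed)
  switch(preset,
    none = zero,
    drift = { zero$drift_speed <- 30; zero },
    tremor = { zero$tremor_amplitude <- 2.5; zero },
    microsaccade = { zero$microsaccade_rate <- 2; zero },
    full = motion_params(seed = seed))
}

#' Simulate a fixational eye-motion trace
#'
#' One translation sample is generated per B-scan interval (B-scans are
#' treated as rigid, so all A-lines of a B-scan share a sample). The trace is
#' the sum of a piecewise-linear random-walk drift, a random-phase sinusoidal
#' tremor in x and y, Poisson-scheduled microsaccade ramps, and a sinusoidal
#' axial ripple in z. Torsion angles (deg) and isotropic scales are drawn once
#' per volume.
#'
#' The `m*_um` columns are the eye-motion offsets added to the scanner
#' position when sampling the retina. The `d*_px` columns restate them in the
#' registration sign convention (displacement of a target acquired under this
#' motion relative to a motion-free reference): `d = -m / pitch`.
#'
#' @param duration trace length in seconds (> 0).
#' @param params a [motion_params()] object.
#' @param bscan_rate B-scan rate in Hz.
#' @param n_volumes number of volumes acquired during the trace (one torsion
#'   angle and scale drawn per volume).
#' @param pitch pixel pitch `c(x=, y=, z=)` in um/px used for the `d*_px`
#'   ground-truth columns.
#' @return an object of class `motion_trace`.
#' @export
simulate_motion <- function(duration, params = motion_params(),
                            bscan_rate = 1100, n_volumes = 1,
                            pitch = c(x = 1, y = 1, z = 1)) {
  if (duration <= 0) stopf("duration must be > 0")
  n <- as.integer(ceiling(duration * bscan_rate)) + 1L
  t <- (seq_len(n) - 1L) / bscan_rate  # seconds

  with_seed(params$seed, {
    mx <- my <- mz <- numeric(n)

    if (params$drift_speed > 0) {
      seg <- 0.5  # drift heading persists ~0.5 s
      n_seg <- max(1L, ceiling(duration / seg))
      ang <- stats::runif(n_seg, 0, 2 * pi)
      vx <- params$drift_speed * cos(ang)
      vy <- params$drift_speed * sin(ang)
      idx <- pmin(floor(t / seg) + 1L, n_seg)
      dt <- 1 / bscan_rate
      mx <- mx + cumsum(c(0, vx[idx[-n]])) * dt
      my <- my + cumsum(c(0, vy[idx[-n]])) * dt
    }

    if (params$tremor_amplitude > 0) {
      # narrowband stochastic oscillation: a sinusoid at the tremor
      # frequency whose complex envelope wanders with ~5-cycle coherence
      # (physiological tremor is band-limited noise, not a phase-locked
      # tone; a fixed phase would alias against the volume rate)
      w <- 2 * pi / (params$tremor_period / 1000)
      tau_c <- 5 * params$tremor_period / 1000
      rho <- exp(-1 / (bscan_rate * tau_c))
      band <- function() {
        er <- stats::rnorm(n); ei <- stats::rnorm(n)
        for (k in 2:n) {
          er[k] <- rho * er[k - 1] + sqrt(1 - rho^2) * er[k]
          ei[k] <- rho * ei[k - 1] + sqrt(1 - rho^2) * ei[k]
        }
        params$tremor_amplitude * (er * cos(w * t) - ei * sin(w * t)) / sqrt(2)
      }
      mx <- mx + band()
      my <- my + band()
    }

    if (params$microsaccade_rate > 0 && params$microsaccade_amplitude > 0) {
      n_ev <- stats::rpois(1, params$microsaccade_rate * duration)
      if (n_ev > 0) {
        starts <- sort(stats::runif(n_ev, 0, duration))
        dur <- params$microsaccade_duration / 1000
        # drop events overlapping the previous one
        keep <- c(TRUE, diff(starts) > dur)
        starts <- starts[keep]
        for (s0 in starts) {
          u <- (t - s0) / dur
          ramp <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
          ang <- stats::runif(1, 0, 2 * pi)
          mx <- mx + params$microsaccade_amplitude * cos(ang) * ramp
          my <- my + params$microsaccade_amplitude * sin(ang) * ramp
        }
        saccades <- starts
      } else saccades <- numeric(0)
    } else saccades <- numeric(0)

    if (params$axial_amplitude > 0) {
      w <- 2 * pi / params$axial_period
      mz <- mz + params$axial_amplitude * sin(w * t + stats::runif(1, 0, 2 * pi))
    }

    # torsion and scale are effectively constant within one video (~5 s):
    # one draw per trace, replicated across its volumes
    torsion <- rep(if (params$torsion_sd > 0)
      stats::rnorm(1, 0, params$torsion_sd) else 0, n_volumes)
    scale <- rep(if (params$scale_sd > 0)
      1 + stats::rnorm(1, 0, params$scale_sd) else 1, n_volumes)

    structure(list(bscan_index = seq_len(n), t_ms = t * 1000,
                   mx_um = mx, my_um = my, mz_um = mz,
                   dx_px = -mx / pitch[["x"]],
                   dy_px = -my / pitch[["y"]],
                   dz_px = -mz / pitch[["z"]],
                   torsion_deg = torsion, scale = scale,
                   saccade_starts_s = saccades,
                   saccade_duration_s = params$microsaccade_duration / 1000,
                   bscan_rate = bscan_rate, params = params),
              class = "motion_trace")
  })
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf(
    "motion_trace: %d samples over %.3f s, %d volume(s), %d microsaccade(s)\n",
    length(x$t_ms), max(x$t_ms) / 1000, length(x$torsion_deg),
    length(x$saccade_starts_s)))
  invisible(x)
}
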