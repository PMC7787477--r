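# Cone-mosaic phantom, eye-motion simulator and raster acquisition.

test_that("phantom lattice has the requested nearest-neighbour spacing and is deterministic", {
  ph <- build_phantom(size = c(x = 120, y = 120, z = 100), cone_spacing = 6,
                      mosaic_jitter = 0, seed = 7)
  cen <- ph$centers
  # interior cones: at least one lattice period away from the (extended) rim
  inside <- cen[, 1] > min(cen[, 1]) + 6 & cen[, 1] < max(cen[, 1]) - 6 &
    cen[, 2] > min(cen[, 2]) + 6 & cen[, 2] < max(cen[, 2]) - 6
  idx <- which(inside)[seq(1, sum(inside), length.out = 50)]
  nn <- vapply(idx, function(k) {
    d <- sqrt((cen[, 1] - cen[k, 1])^2 + (cen[, 2] - cen[k, 2])^2)
    min(d[d > 1e-9])
  }, numeric(1))
  expect_true(all(abs(nn - 6) < 1e-6))

  # roughly (120/6) * (120/(6*sqrt(3)/2)) cones inside the nominal field
  in_field <- sum(cen[, 1] >= 0 & cen[, 1] <= 120 &
                    cen[, 2] >= 0 & cen[, 2] <= 120)
  expect_gt(in_field, 0.8 * (120 / 6) * (120 / (6 * sqrt(3) / 2)))

  ph2 <- build_phantom(size = c(x = 120, y = 120, z = 100), cone_spacing = 6,
                       mosaic_jitter = 0, seed = 7)
  expect_identical(ph$mosaic, ph2$mosaic)
  expect_identical(ph$centers, ph2$centers)

  expect_error(build_phantom(cone_spacing = -1), "cone_spacing")
  expect_error(build_phantom(size = c(x = 30, y = 30, z = 50),
                             cone_spacing = 6), "10x10")
})

test_that("en-face mosaic spectral peak sits on Yellott's ring within one bin", {
  ph <- small_phantom()
  g <- seq(0, 79, by = 1)
  img <- outer(g, g, function(x, y) eval_phantom(ph, x, y, 40))
  prof <- radial_power_profile(img, pitch = c(1, 1))
  f_peak <- prof$freq[which.max(prof$power)]
  bin <- prof$freq[2] - prof$freq[1]
  expect_lt(abs(f_peak - cone_peak_frequency(6)), bin + 1e-9)
})

test_that("zero motion parameters give a constant trace; seeds are reproducible", {
  tr <- simulate_motion(0.1, motion_preset("none"), bscan_rate = 1100,
                        n_volumes = 2)
  expect_true(all(tr$mx_um == 0) && all(tr$my_um == 0) && all(tr$mz_um == 0))
  expect_identical(tr$torsion_deg, c(0, 0))
  expect_identical(tr$scale, c(1, 1))
  expect_true(all(diff(tr$t_ms) > 0))

  p <- motion_params(seed = 42)
  t1 <- simulate_motion(0.3, p, 1100, n_volumes = 2)
  t2 <- simulate_motion(0.3, p, 1100, n_volumes = 2)
  expect_identical(t1, t2)
  expect_error(simulate_motion(0, p), "duration")
  expect_error(motion_params(drift_speed = -1), ">= 0")
})

test_that("a microsaccade accrues its full amplitude across the event", {
  p <- motion_params(drift_speed = 0, tremor_amplitude = 0,
                     microsaccade_rate = 3, microsaccade_amplitude = 60,
                     microsaccade_duration = 25, axial_amplitude = 0,
                     torsion_sd = 0, scale_sd = 0, seed = 9)
  tr <- simulate_motion(2, p, bscan_rate = 1100)
  expect_gt(length(tr$saccade_starts_s), 0)
  t_s <- tr$t_ms / 1000
  for (s0 in tr$saccade_starts_s) {
    before <- max(which(t_s <= s0))
    after <- min(which(t_s >= s0 + 0.025))
    if (!is.finite(after)) next
    jump <- sqrt((tr$mx_um[after] - tr$mx_um[before])^2 +
                   (tr$my_um[after] - tr$my_um[before])^2)
    expect_lt(abs(jump - 60), 60 / (0.025 * 1100) + 1e-6)
  }
})

test_that("zero-motion acquisition equals direct regular phantom sampling", {
  ph <- small_phantom()
  sc <- scan_params(n_x = 32, n_z = 40, n_y = 16,
                    pitch = c(x = 1, y = 1, z = 1))
  tr <- simulate_motion(0.05, motion_preset("none"), sc$bscan_rate,
                        pitch = sc$pitch)
  acq <- acquire_volume(ph, tr, sc, 1, noise_sd = 0, noise_floor = 0)
  direct <- array(0, c(40, 32, 16))
  for (i in 1:16) for (a in 1:32)
    direct[, a, i] <- eval_phantom(ph, a - 1, i - 1, 0:39)
  expect_equal(acq$volume$intensity, direct, tolerance = 1e-12)
  expect_equal(nrow(acq$truth), 16)   # one ground-truth row per B-scan
  expect_true(all(acq$truth$dy_px == 0))
})

test_that("constant y drift shears the en-face image with the imposed slope", {
  ph <- small_phantom()
  sc <- scan_params(n_x = 48, n_z = 40, n_y = 24,
                    pitch = c(x = 1, y = 1, z = 1))
  v_px <- 0.5  # px per B-scan
  tr <- simulate_motion(0.05, motion_preset("none"), sc$bscan_rate,
                        pitch = sc$pitch)
  drift <- tr
  k <- round(tr$t_ms / 1000 * sc$bscan_rate)
  drift$my_um <- v_px * k
  drift$dy_px <- -drift$my_um
  acq <- acquire_volume(ph, drift, sc, 1, noise_sd = 0, noise_floor = 0)
  # B-scan i samples rows y = (i-1) + v*(i-1): against a zero-motion render,
  # row i of the drifted volume equals row 1 + (1+v)*(i-1) of the phantom
  still <- acquire_volume(ph, tr, sc, 1, noise_sd = 0, noise_floor = 0)
  for (i in c(5, 9, 17)) {
    yy <- (i - 1) * (1 + v_px)
    direct <- vapply(1:48, function(a)
      mean(eval_phantom(ph, a - 1, yy, 0:39)), numeric(1))
    got <- apply(acq$volume$intensity[, , i], 2, mean)
    expect_gt(stats::cor(got, direct), 0.999)
  }
  expect_false(isTRUE(all.equal(acq$volume$intensity, still$volume$intensity)))
})

test_that("all A-lines within a B-scan share one motion sample", {
  ph <- small_phantom()
  sc <- scan_params(n_x = 32, n_z = 40, n_y = 8,
                    pitch = c(x = 1, y = 1, z = 1))
  tr <- simulate_motion(0.05, motion_preset("none"), sc$bscan_rate,
                        pitch = sc$pitch)
  step <- tr
  # x motion jumping by +3 um exactly at every B-scan boundary
  k <- round(tr$t_ms / 1000 * sc$bscan_rate)
  step$mx_um <- 3 * k
  step$dx_px <- -step$mx_um
  acq <- acquire_volume(ph, step, sc, 1, noise_sd = 0, noise_floor = 0)
  # each B-scan must equal a rigid resampling at its single offset
  for (i in c(2, 5)) {
    direct <- array(0, c(40, 32))
    for (a in 1:32)
      direct[, a] <- eval_phantom(ph, (a - 1) + 3 * (i - 1), i - 1, 0:39)
    expect_equal(acq$volume$intensity[, , i], direct, tolerance = 1e-12)
  }
})

test_that("acquisition fails cleanly when the trace is too short", {
  ph <- small_phantom()
  sc <- scan_params(n_x = 16, n_z = 16, n_y = 64)
  tr <- simulate_motion(0.01, motion_preset("none"), sc$bscan_rate)
  expect_error(acquire_volume(ph, tr, sc, 1), "does not cover")
})
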