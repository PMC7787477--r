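# Shared fixtures. Heavy simulation/registration products are built lazily
# and cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small phantom reused by fast tests.
small_phantom <- function() {
  cached("small_phantom", function()
    build_phantom(size = c(x = 80, y = 80, z = 100), cone_spacing = 6,
                  seed = 2))
}

# A tiny zero-motion volume from the small phantom; mild speckle-like noise
# by default (real OCT data is broadband).
tiny_volume <- function(seed = 1, n_y = 24, noise_sd = 0.15) {
  ph <- small_phantom()
  sc <- scan_params(n_x = 48, n_z = 48, n_y = n_y,
                    pitch = c(x = 1, y = 1, z = 1))
  tr <- simulate_motion(n_y / sc$bscan_rate + 0.01, motion_preset("none"),
                        bscan_rate = sc$bscan_rate, pitch = sc$pitch)
  acquire_volume(ph, tr, sc, 1, noise_sd = noise_sd, noise_floor = 0,
                 seed = seed)$volume
}

# Drift+tremor dataset at the scale used for the B-scan-stage parameter
# recovery (10 volumes of 64 B-scans x 96 z x 96 x), with one extra volume
# containing a single microsaccade.
bscan_recovery_fixture <- function() {
  cached("bscan_recovery", function() {
    ph <- build_phantom(size = c(x = 140, y = 140, z = 110),
                        cone_spacing = 6, seed = 3)
    sc <- scan_params(n_x = 96, n_z = 96, n_y = 64,
                      pitch = c(x = 1, y = 1, z = 1))
    pp <- motion_params(drift_speed = 30, tremor_amplitude = 2.5,
                        microsaccade_rate = 0, axial_amplitude = 5,
                        torsion_sd = 0, scale_sd = 0, seed = 11)
    ds <- simulate_dataset(ph, sc, pp, n_videos = 1, volumes_per_video = 10,
                           noise_sd = 0.2, noise_floor = 0.01, seed = 5)
    ds$volumes <- lapply(ds$volumes, normalize_intensity)

    # one additional volume whose trace contains a single 25-ms microsaccade
    # of 30 um starting mid-volume (displacement ramp held thereafter)
    tr <- ds$traces[[1]]
    n <- length(tr$t_ms)
    t_s <- tr$t_ms / 1000
    s0 <- 30 / sc$bscan_rate            # saccade start: B-scan 30 of volume 1
    u <- (t_s - s0) / 0.025
    ramp <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
    sac <- tr
    sac$mx_um <- tr$mx_um + 30 * ramp * cos(0.7)
    sac$my_um <- tr$my_um + 30 * ramp * sin(0.7)
    sac$dx_px <- -sac$mx_um; sac$dy_px <- -sac$my_um
    acq <- acquire_volume(ph, sac, sc, 1, noise_sd = 0.2,
                          noise_floor = 0.01, video = 1, seed = 77)
    list(ds = ds, scan = sc, phantom = ph,
         saccade_volume = normalize_intensity(acq$volume),
         saccade_truth = acq$truth,
         saccade_bscans = which(ramp[round(t_s[1:64] * sc$bscan_rate) + 1] > 0 &
                                  ramp[round(t_s[1:64] * sc$bscan_rate) + 1] < 1))
  })
}

# Registrations of the recovery fixture against its selected reference.
bscan_registrations <- function() {
  cached("bscan_registrations", function() {
    fx <- bscan_recovery_fixture()
    vols <- fx$ds$volumes
    ref <- select_reference(vols)
    disp <- lapply(seq_along(vols), function(T)
      register_bscans(vols[[T]], vols[[ref]], s = 10, d = 6))
    list(ref = ref, disp = disp)
  })
}

# Expected per-B-scan displacements for a target/reference pair from the
# simulator ground truth (registration convention; j matched by content).
expected_displacements <- function(truth, target_vol, ref_vol) {
  gt_t <- truth[truth$volume == target_vol, ]
  gt_r <- truth[truth$volume == ref_vol, ]
  pos_t <- gt_t$i - gt_t$dy_px
  pos_r <- gt_r$i - gt_r$dy_px
  j <- vapply(pos_t, function(p) which.min(abs(pos_r - p)), integer(1))
  data.frame(i = gt_t$i, j = j,
             dy = gt_t$i - j,
             dx = gt_t$dx_px - gt_r$dx_px[j],
             dz = gt_t$dz_px - gt_r$dz_px[j])
}

# Per-B-scan displacement errors of an estimate against ground truth,
# evaluated at the estimate's own matched reference B-scan: tremor can fold
# the reference's slow-axis sampling so that several reference B-scans carry
# (nearly) the same retinal content, and any of them is a correct match.
# The y error is the retinal-position mismatch of the chosen pair; x/z
# errors compare the in-plane estimate with the truth for that pair.
displacement_errors <- function(truth, disp, target_vol, ref_vol) {
  gt_t <- truth[truth$volume == target_vol, ]
  gt_r <- truth[truth$volume == ref_vol, ]
  pos_t <- gt_t$i - gt_t$dy_px
  pos_r <- gt_r$i - gt_r$dy_px
  d <- disp$displacements
  j_est <- d$j
  ok <- d$included & !is.na(j_est)
  data.frame(
    i = d$i,
    included = ok,
    ey = ifelse(ok, pos_r[j_est] - pos_t, NA_real_),
    ex = ifelse(ok, d$dx - (gt_t$dx_px - gt_r$dx_px[j_est]), NA_real_),
    ez = ifelse(ok, d$dz - (gt_t$dz_px - gt_r$dz_px[j_est]), NA_real_))
}

# Global-stage fixture, part A: strongly moving volumes (3 videos x 3),
# no torsion/scale, noiseless -- every reference carries real distortion.
global_tau_fixture <- function() {
  cached("global_tau", function() {
    ph <- build_phantom(size = c(x = 110, y = 110, z = 110),
                        cone_spacing = 6, seed = 3)
    sc <- scan_params(n_x = 64, n_z = 64, n_y = 48,
                      pitch = c(x = 1, y = 1, z = 1))
    pp <- motion_params(drift_speed = 20, tremor_amplitude = 1.5,
                        microsaccade_rate = 0, axial_amplitude = 3,
                        torsion_sd = 0, scale_sd = 0, seed = 1)
    volumes <- list(); video <- integer(0); truth <- list()
    for (v in 1:3) {
      p <- pp; p$seed <- 100 + v
      tr <- simulate_motion(3 / sc$volume_rate + 0.01, p, sc$bscan_rate,
                            n_volumes = 3, pitch = sc$pitch)
      for (w in 1:3) {
        acq <- acquire_volume(ph, tr, sc, w, noise_sd = 0, noise_floor = 0,
                              video = v, seed = v * 10 + w)
        volumes[[length(volumes) + 1]] <- acq$volume
        tt <- acq$truth; tt$volume <- length(volumes)
        truth[[length(truth) + 1]] <- tt
        video <- c(video, v)
      }
    }
    volumes <- lapply(volumes, normalize_intensity)
    mrd <- multi_reference_register(volumes, video, references = "auto",
                                    s = 10, d = 6)
    p <- compute_p(mrd)
    sol <- solve_reference_offsets(p, mrd$references)
    tau <- global_bscan_coords(p, sol$eps, n_t = length(volumes),
                               n_y = mrd$n_y)
    list(volumes = volumes, video = video, truth = do.call(rbind, truth),
         scan = sc, phantom = ph, mrd = mrd, p = p, sol = sol, tau = tau)
  })
}

# Global-stage fixture, part B: torsion/scale chain across 4 videos with
# mild translation motion.
global_affine_fixture <- function() {
  cached("global_affine", function() {
    ph <- build_phantom(size = c(x = 110, y = 110, z = 110),
                        cone_spacing = 6, seed = 3)
    sc <- scan_params(n_x = 64, n_z = 64, n_y = 48,
                      pitch = c(x = 1, y = 1, z = 1))
    pp <- motion_params(drift_speed = 5, tremor_amplitude = 0.4,
                        microsaccade_rate = 0, axial_amplitude = 1,
                        torsion_sd = 0, scale_sd = 0, seed = 2)
    theta <- c(0, 0.4, 0.7, 1.0)
    scl <- c(1, 1.005, 1.015, 1.02)
    volumes <- list(); video <- integer(0)
    for (v in 1:4) {
      p <- pp; p$seed <- 200 + v
      tr <- simulate_motion(3 / sc$volume_rate + 0.01, p, sc$bscan_rate,
                            n_volumes = 3, pitch = sc$pitch)
      tr$torsion_deg[] <- theta[v]; tr$scale[] <- scl[v]
      for (w in 1:3) {
        acq <- acquire_volume(ph, tr, sc, w, noise_sd = 0, noise_floor = 0,
                              video = v, seed = v * 10 + w)
        volumes[[length(volumes) + 1]] <- acq$volume
        video <- c(video, v)
      }
    }
    volumes <- lapply(volumes, normalize_intensity)
    mrd <- multi_reference_register(volumes, video, references = "auto",
                                    s = 10, d = 6)
    p <- compute_p(mrd)
    sol <- solve_reference_offsets(p, mrd$references)
    tau <- global_bscan_coords(p, sol$eps, n_t = length(volumes),
                               n_y = mrd$n_y)
    aff <- estimate_video_affines(volumes, tau, video)
    list(volumes = volumes, video = video, scan = sc, theta = theta,
         scl = scl, mrd = mrd, tau = tau, aff = aff)
  })
}

# Longest contiguous run of TRUE in a logical vector (indices).
longest_run <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values)
  if (!length(ok)) return(integer(0))
  b <- ok[which.max(r$lengths[ok])]
  starts[b]:ends[b]
}

# Crop an en-face image (x by y) to given y slots and trimmed x interior:
# comparisons between registered and unregistered averages are made over
# pixels covered by both, away from shift-induced zero borders.
trim_enface <- function(img, slots, xtrim = 12) {
  unclass(img)[(xtrim + 1):(nrow(img) - xtrim), slots]
}

# Centered crop to a common extent.
center_crop <- function(img, ext) {
  d <- dim(img)
  r0 <- (d[1] - ext[1]) %/% 2
  c0 <- (d[2] - ext[2]) %/% 2
  unclass(img)[r0 + seq_len(ext[1]), c0 + seq_len(ext[2])]
}

# Image-quality ordering experiment: 2 videos x 10
# volumes at the acquisition protocol's volume rate (2.4 vol/s, which
# decorrelates tremor phase between volumes), speckle noise, plus one
# deliberately distorted reference volume -- a volume with the population's
# typical motion rather than the quality-metric optimum -- used by the
# single-reference arm. The global arm uses five references.
global_snr_fixture <- function() {
  cached("global_snr", function() {
    ph <- build_phantom(size = c(x = 110, y = 110, z = 110),
                        cone_spacing = 6, seed = 3)
    sc <- scan_params(n_x = 64, n_z = 64, n_y = 48,
                      pitch = c(x = 1, y = 1, z = 1), volume_rate = 2.4)
    pp <- motion_params(drift_speed = 10, tremor_amplitude = 1.5,
                        microsaccade_rate = 0, axial_amplitude = 2,
                        torsion_sd = 0, scale_sd = 0, seed = 1)
    volumes <- list(); video <- integer(0)
    for (v in 1:2) {
      p <- pp; p$seed <- 100 + v
      tr <- simulate_motion(10 / sc$volume_rate + 0.01, p, sc$bscan_rate,
                            n_volumes = 10, pitch = sc$pitch)
      for (w in 1:10) {
        acq <- acquire_volume(ph, tr, sc, w, noise_sd = 0.2,
                              noise_floor = 0.01, video = v,
                              seed = 1000 + v * 10 + w)
        volumes[[length(volumes) + 1]] <- acq$volume
        video <- c(video, v)
      }
    }
    pd <- motion_params(drift_speed = 10, tremor_amplitude = 1.5,
                        microsaccade_rate = 0, axial_amplitude = 2,
                        torsion_sd = 0, scale_sd = 0, seed = 300)
    trd <- simulate_motion(1 / sc$volume_rate + 0.01, pd, sc$bscan_rate,
                           n_volumes = 1, pitch = sc$pitch)
    acq <- acquire_volume(ph, trd, sc, 1, noise_sd = 0.2,
                          noise_floor = 0.01, video = 3, seed = 999)
    volumes[[length(volumes) + 1]] <- acq$volume
    video <- c(video, 3)
    volumes <- lapply(volumes, normalize_intensity)
    dref <- length(volumes)
    refs <- c(dref, 3, 6, 13, 16)
    mrd <- multi_reference_register(volumes, video, references = refs,
                                    s = 10, d = 6)
    p <- compute_p(mrd)
    sol <- solve_reference_offsets(p, mrd$references)
    tau <- global_bscan_coords(p, sol$eps, n_t = length(volumes),
                               n_y = mrd$n_y)
    list(volumes = volumes, video = video, mrd = mrd, tau = tau,
         dref = dref, scan = sc)
  })
}

# Fill interior slow-axis gap slots of an en-face image by per-row linear
# interpolation and crop to the covered range (used for spectral metrics at
# low averaging counts, where a contiguous covered rectangle is required;
# interpolated rows are blurrier, so this is conservative for the
# registered average).
fill_gaps_y <- function(img, covered) {
  img <- unclass(img)
  obs <- which(covered)
  lo <- min(obs); hi <- max(obs)
  gaps <- setdiff(lo:hi, obs)
  if (length(gaps)) {
    for (r in seq_len(nrow(img)))
      img[r, gaps] <- stats::approx(obs, img[r, obs], gaps)$y
  }
  list(img = img, range = lo:hi)
}
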