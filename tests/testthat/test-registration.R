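# Coarse-to-fine B-scan registration, filtering, volume construction.

test_that("coarse trace of a volume against itself is all zero and valid", {
  v <- tiny_volume(n_y = 32)
  ct <- coarse_trace(v, v, s = 8, d = 4)
  expect_true(ct$ok)
  expect_true(all(ct$samples$dY[ct$samples$valid] == 0))
  expect_true(all(ct$samples$dX[ct$samples$valid] == 0))
})

test_that("trend filter drops only samples deviating from the motion trend", {
  # a single interior outlier (.., 0, 25, 2, ..) is dropped alone
  expect_identical(aoreg:::trend_keep(c(0, 0, 25, 2, 2), s = 10),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # an edge outlier is peeled without condemning its neighbour
  expect_identical(aoreg:::trend_keep(c(30, 1, 2, 2, 3), s = 10),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(aoreg:::trend_keep(c(1, 2, 2, 3, -40), s = 10),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # a smooth trend with steps below s survives intact
  expect_true(all(aoreg:::trend_keep(c(0, 4, 9, 13, 18), s = 10)))
})

test_that("position prediction interpolates and extrapolates linearly", {
  v <- tiny_volume(n_y = 32)
  ct <- coarse_trace(v, v, s = 8, d = 4)
  # overwrite with two synthetic valid samples: (center 8, dY 0), (center 24, dY 4)
  ct$samples <- ct$samples[1:2, ]
  ct$samples$center <- c(8L, 24L)
  ct$samples$dY <- c(0, 4)
  ct$samples$valid <- TRUE
  ct$ok <- TRUE
  pred <- predict_positions(ct, n_bscans = 32)
  expect_equal(pred$dy_pred[16], 2)
  expect_equal(pred$y_pred[16], 14)
  expect_equal(pred$dy_pred[c(8, 24)], c(0, 4))
  # linear extension below the first sample: dy(0-like index 1) continues the slope
  slope <- 4 / 16
  expect_equal(pred$dy_pred[1], 0 - slope * 7)
  # all-zero samples predict the identity
  ct$samples$dY <- c(0, 0)
  pred0 <- predict_positions(ct, n_bscans = 32)
  expect_equal(pred0$y_pred, 1:32)
})

test_that("fine NCC self-registration yields zero displacement and rho 1", {
  v <- tiny_volume(n_y = 24)
  pred <- data.frame(i = 1:24, dy_pred = 0, y_pred = 1:24)
  disp <- ncc_fine(v, v, pred, w_y = 8)
  d <- disp$displacements
  expect_true(all(d$matched))
  expect_true(all(d$dx == 0 & d$dy == 0 & d$dz == 0))
  expect_true(all(abs(d$ncc - 1) < 1e-9))
})

test_that("search window spans 17 candidates at w_y = 8 away from boundaries", {
  # candidate count is visible through which j can win: plant the best match
  # at the window edge and verify it is found iff within round(y_pred) +/- 8
  v <- tiny_volume(n_y = 40)
  pred <- data.frame(i = 1:40, dy_pred = 0, y_pred = 1:40)
  disp <- ncc_fine(v, v, pred, w_y = 8)
  d <- disp$displacements
  expect_true(all(d$dy == 0))
  # forcing predictions 8 away still recovers the true j for interior B-scans
  pred_off <- data.frame(i = 1:40, dy_pred = -8, y_pred = (1:40) + 8)
  d_off <- ncc_fine(v, v, pred_off, w_y = 8)$displacements
  interior <- 9:32
  expect_true(all(d_off$dy[interior] == 0))
  # w_y = 1 with the same offset cannot reach the true match
  d_narrow <- ncc_fine(v, v, pred_off, w_y = 1)$displacements
  expect_true(all(d_narrow$dy[interior] != 0))
})

test_that("outlier filter applies the NCC floor and the windowed-SD rule", {
  v <- tiny_volume(n_y = 30)
  pred <- data.frame(i = 1:30, dy_pred = 0, y_pred = 1:30)
  disp <- ncc_fine(v, v, pred, w_y = 4)

  # constant displacements, strong coefficients: nothing excluded
  f <- filter_outliers(disp, window_ms = 20, sigma_max_px = 4, ncc_min = 0.3)
  expect_true(all(f$displacements$included))

  # a single rho below the floor excludes exactly that B-scan
  low <- disp; low$displacements$ncc[7] <- 0.25
  f2 <- filter_outliers(low, ncc_min = 0.3)
  expect_false(f2$displacements$included[7])
  expect_true(all(f2$displacements$included[-7]))

  # a 30 px jump in dx against flat neighbours trips the windowed SD
  jump <- disp; jump$displacements$dx[15] <- 30
  f3 <- filter_outliers(jump, window_ms = 20, sigma_max_px = 4)
  expect_false(f3$displacements$included[15])
  # direct windowed-SD oracle at the jump location
  w <- max(5L, round(20 / 1000 * v$bscan_rate)); h <- w %/% 2
  win <- max(1, 15 - h):min(30, 15 + h)
  expect_equal(f3$displacements$sigma_delta[15],
               stats::sd(jump$displacements$dx[win]))
  expect_gt(f3$displacements$sigma_delta[15], 4)
})

test_that("registered-volume construction places, collides and reports conservatively", {
  v <- tiny_volume(n_y = 20)
  mk_disp <- function(dy, dx = 0, dz = 0, ncc = 0.9) {
    d <- data.frame(i = 1:20, j = pmin(pmax(1:20 - dy, 1), 20), dx = dx,
                    dy = dy, dz = dz, ncc = ncc, y_pred = 1:20,
                    matched = TRUE, sigma_delta = 0, included = TRUE)
    structure(list(displacements = d, bscan_rate = v$bscan_rate),
              class = "bscan_displacements")
  }
  # zero displacements reproduce the input with an empty gap mask
  r0 <- construct_registered(v, mk_disp(0))
  expect_identical(r0$volume$intensity, v$intensity)
  expect_false(any(r0$gap_mask))
  expect_equal(r0$report$placed + r0$report$gaps, 20)

  # B-scans 10 and 11 both mapped to slot 10: last acquired (11) wins
  disp <- mk_disp(0)
  disp$displacements$dy[11] <- 1   # slot = 11 - 1 = 10
  r1 <- construct_registered(v, disp)
  expect_equal(r1$volume$intensity[, , 10], v$intensity[, , 11])
  expect_true(r1$gap_mask[11])
  expect_equal(r1$report$collided, 1)
  expect_equal(r1$report$placed + r1$report$gaps, 20)

  # in-plane shifts are applied as -(dx, dz) with zero fill
  disp2 <- mk_disp(0, dx = 3, dz = -2)
  r2 <- construct_registered(v, disp2)
  expect_equal(r2$volume$intensity[5, 10, 4], v$intensity[3, 13, 4])

  # all-excluded input signals an empty volume
  de <- mk_disp(0); de$displacements$included <- FALSE
  re <- construct_registered(v, de)
  expect_true(re$report$empty)
  expect_equal(re$report$gaps, 20)
})

test_that("averaging respects gap masks and reduces noise as 1/sqrt(N)", {
  v <- tiny_volume(n_y = 12)
  wrap <- function(vol, gaps = integer(0)) {
    gm <- rep(FALSE, 12); gm[gaps] <- TRUE
    list(volume = vol, gap_mask = gm,
         report = list(empty = FALSE))
  }
  # single volume with no gaps: identity
  a1 <- average_registered(list(wrap(v)))
  expect_identical(a1$volume$intensity, v$intensity)
  expect_true(all(a1$count == 1))

  # complementary gaps: full coverage, counts 1 at former gaps
  v2 <- v; v2$intensity <- v2$intensity * 2
  a2 <- average_registered(list(wrap(v, gaps = 1:6), wrap(v2, gaps = 7:12)))
  expect_equal(a2$count, rep(1, 12))
  expect_identical(a2$volume$intensity[, , 1], v2$intensity[, , 1])
  expect_identical(a2$volume$intensity[, , 12], v$intensity[, , 12])
  a3 <- average_registered(list(wrap(v), wrap(v2)))
  expect_true(all(a3$count == 2))
  expect_equal(a3$volume$intensity, (v$intensity + v2$intensity) / 2)

  # Monte-Carlo: per-voxel SD of the mean of N noisy copies ~ 1/sqrt(N)
  set.seed(5)
  base <- v$intensity
  noisy <- function() { w <- v; w$intensity <- base +
    array(stats::rnorm(length(base), sd = 0.1), dim(base)); wrap(w) }
  sd_of_mean <- function(N) {
    avg <- average_registered(replicate(N, noisy(), simplify = FALSE))
    stats::sd(avg$volume$intensity - base)
  }
  s4 <- sd_of_mean(4); s16 <- sd_of_mean(16)
  expect_equal(s4 / s16, 2, tolerance = 0.15)
})

test_that("self-registration through the full cascade is exact", {
  v <- tiny_volume(n_y = 32)
  disp <- register_bscans(v, v, s = 8, d = 4)
  d <- disp$displacements
  expect_true(all(d$included))
  expect_true(all(d$dx == 0 & d$dy == 0 & d$dz == 0))
  expect_true(all(abs(d$ncc - 1) < 1e-9))
})

test_that("integer-translated targets register with exactly the imposed shift", {
  v <- tiny_volume(n_y = 32)
  sh <- c(dz = 2, dx = -3, dy = 4)
  arr <- array(0, dim(v$intensity))
  for (i in 1:32) {
    src <- i - sh[["dy"]]
    if (src >= 1 && src <= 32) {
      bs <- v$intensity[, , src]
      out <- matrix(0, nrow(bs), ncol(bs))
      rr <- max(1, 1 + sh[["dz"]]):min(nrow(bs), nrow(bs) + sh[["dz"]])
      cc <- max(1, 1 + sh[["dx"]]):min(ncol(bs), ncol(bs) + sh[["dx"]])
      out[rr, cc] <- bs[rr - sh[["dz"]], cc - sh[["dx"]]]
      arr[, , i] <- out
    }
  }
  t_vol <- v; t_vol$intensity <- arr
  disp <- register_bscans(t_vol, v, s = 8, d = 4)
  d <- disp$displacements
  interior <- d$included & d$i > 6 & d$i < 27
  expect_gt(sum(interior), 10)
  expect_true(all(d$dy[interior] == 4))
  expect_true(all(d$dx[interior] == -3))
  expect_true(all(d$dz[interior] == 2))
})
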