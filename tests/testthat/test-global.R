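# Multi-reference global solver: reference motion, p, offsets, tau, chi,
# rendering, and the en-face affine estimator.

# Construct a synthetic multi_ref object from hand-written displacement
# tables: disp_tables[[as.character(R)]][[T]] is a data.frame with columns
# i, j, dx, dy, dz (all rows included).
make_mrd <- function(disp_tables, n_y, n_x = 16, n_t = NULL) {
  refs <- as.integer(names(disp_tables))
  n_t <- n_t %||% max(vapply(disp_tables, length, integer(1)))
  pairs <- list()
  registered <- matrix(FALSE, n_t, length(refs),
                       dimnames = list(NULL, names(disp_tables)))
  for (k in names(disp_tables)) {
    pr <- vector("list", n_t)
    for (T in seq_len(n_t)) {
      df <- disp_tables[[k]][[T]]
      if (is.null(df)) next
      df$ncc <- 1; df$matched <- TRUE; df$included <- TRUE
      df$y_pred <- df$i; df$sigma_delta <- 0
      pr[[T]] <- structure(list(displacements = df, bscan_rate = 1100),
                           class = "bscan_displacements")
      registered[T, k] <- TRUE
    }
    pairs[[k]] <- pr
  }
  structure(list(pairs = pairs, references = refs, registered = registered,
                 fraction = mean(rowSums(registered) > 0),
                 video = rep(1L, n_t), n_y = n_y, n_x = n_x),
            class = "multi_ref")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference motion averages matched displacements by reference B-scan", {
  n_y <- 6
  # two targets contributing +v and -v at the same j -> a = 0
  t1 <- data.frame(i = 1:6, j = 1:6, dx = 2, dy = 0, dz = 1)
  t2 <- data.frame(i = 1:6, j = 1:6, dx = -2, dy = 0, dz = -1)
  mrd <- make_mrd(list("1" = list(t1, t2)), n_y)
  rm1 <- reference_motion(mrd, 1)
  expect_true(all(abs(rm1$a) < 1e-12))
  expect_true(all(abs(rm1$b) < 1e-12))
  expect_true(all(abs(rm1$c_R) < 1e-12))

  # group-by-j mean oracle on a random table with re-indexing j = i - dy
  set.seed(21)
  mk <- function() {
    dy <- sample(-1:1, 6, replace = TRUE)
    data.frame(i = 1:6, j = pmin(pmax(1:6 - dy, 1), 6),
               dx = round(stats::rnorm(6), 2), dy = dy,
               dz = round(stats::rnorm(6), 2))
  }
  tabs <- list(mk(), mk(), mk())
  mrd2 <- make_mrd(list("2" = tabs), n_y)
  rm2 <- reference_motion(mrd2, 2)
  all_rows <- do.call(rbind, tabs)
  for (j in sort(unique(all_rows$j))) {
    sel <- all_rows$j == j
    expect_equal(rm2$a[j, 1], mean(all_rows$dx[sel]), tolerance = 1e-12)
    expect_equal(rm2$a[j, 2], mean(all_rows$dy[sel]), tolerance = 1e-12)
  }
  # b is the zero-mean split of a
  expect_equal(colMeans(rm2$b), c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rm2$a, sweep(rm2$b, 2, rm2$c_R, "+"), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("p reduces to scanner positions for zero displacements and is linear", {
  n_y <- 8
  zero <- data.frame(i = 1:8, j = 1:8, dx = 0, dy = 0, dz = 0)
  mrd <- make_mrd(list("1" = list(zero, zero)), n_y)
  p <- compute_p(mrd)
  expect_equal(p$px, rep(0, 16))
  expect_equal(p$py, p$i - (n_y + 1) / 2)
  expect_equal(p$pz, rep(0, 16))

  # adding a constant to all displacements of one reference shifts its p by
  # the negative of that constant (p = a_j - Delta + s with a unchanged by a
  # shared shift... a also shifts, so shift only one target's rows)
  shifted <- zero; shifted$dx <- shifted$dx + 3
  mrd2 <- make_mrd(list("1" = list(shifted, zero)), n_y)
  p2 <- compute_p(mrd2)
  a_x <- 1.5  # mean of 3 and 0 at each j
  expect_equal(p2$px[p2$T == 1], rep(a_x - 3, 8))
  expect_equal(p2$px[p2$T == 2], rep(a_x - 0, 8))

  # element-wise oracle on a random table
  set.seed(22)
  tab <- data.frame(i = 1:8, j = 1:8, dx = stats::rnorm(8),
                    dy = 0, dz = stats::rnorm(8))
  mrd3 <- make_mrd(list("4" = list(tab)), n_y)
  rm <- reference_motion(mrd3, 4)
  p3 <- compute_p(mrd3)
  for (r in seq_len(nrow(p3))) {
    j <- tab$j[r]
    expect_equal(p3$px[r], rm$a[j, 1] - tab$dx[r], tolerance = 1e-12)
    expect_equal(p3$pz[r], rm$a[j, 3] - tab$dz[r], tolerance = 1e-12)
  }
})

test_that("reference-offset least squares matches closed forms and a brute-force minimizer", {
  # identical p across references -> all offsets zero (gauge included)
  p1 <- data.frame(T = rep(1, 6), i = rep(1:3, 2), R = rep(c(1, 2), each = 3),
                   px = rep(c(0.3, -1, 2), 2), py = 0, pz = 0)
  s1 <- solve_reference_offsets(p1)
  expect_equal(s1$eps, matrix(0, 2, 3, dimnames = dimnames(s1$eps)))

  # two references with p_R2 = p_R1 - k on the shared set -> eps_R2 = k
  k <- c(1.7, -0.4, 2.2)
  p2 <- p1
  p2$px[p2$R == 2] <- p2$px[p2$R == 2] - k[1]
  p2$py[p2$R == 2] <- p2$py[p2$R == 2] - k[2]
  p2$pz[p2$R == 2] <- p2$pz[p2$R == 2] - k[3]
  s2 <- solve_reference_offsets(p2)
  expect_equal(unname(s2$eps["2", ]), k, tolerance = 1e-12)
  expect_equal(unname(s2$eps["1", ]), c(0, 0, 0))  # gauge

  # three references with random partial overlaps vs optim() on the cost
  set.seed(23)
  rows <- list()
  for (R in 1:3) {
    sel <- sort(sample(1:10, 7))
    rows[[R]] <- data.frame(T = 1, i = sel, R = R,
                            px = stats::rnorm(7), py = stats::rnorm(7),
                            pz = stats::rnorm(7))
  }
  p3 <- do.call(rbind, rows)
  s3 <- solve_reference_offsets(p3)
  cost <- function(e2, e3, col) {
    e <- c(0, e2, e3)
    tot <- 0
    for (r1 in 1:2) for (r2 in (r1 + 1):3) {
      a <- p3[p3$R == r1, ]; b <- p3[p3$R == r2, ]
      sh <- intersect(a$i, b$i)
      if (!length(sh)) next
      va <- a[match(sh, a$i), col] + e[r1]
      vb <- b[match(sh, b$i), col] + e[r2]
      tot <- tot + sum((va - vb)^2)
    }
    tot
  }
  for (col in c("px", "py", "pz")) {
    o <- stats::optim(c(0, 0), function(e) cost(e[1], e[2], col),
                      method = "BFGS", control = list(reltol = 1e-14))
    ax <- c(px = "x", py = "y", pz = "z")[[col]]
    expect_equal(unname(s3$eps[c("2", "3"), ax]), o$par, tolerance = 1e-3)
  }
})

test_that("gauge and zero-mean invariants of the global coordinates hold", {
  set.seed(24)
  n_y <- 10
  mk <- function() data.frame(i = 1:n_y, j = 1:n_y,
                              dx = stats::rnorm(n_y, 0, 0.5), dy = 0,
                              dz = stats::rnorm(n_y, 0, 0.5))
  tabs1 <- list(mk(), mk(), mk())
  tabs2 <- list(mk(), NULL, mk())
  mrd <- make_mrd(list("1" = tabs1, "3" = tabs2), n_y, n_t = 3)
  p <- compute_p(mrd)
  sol <- solve_reference_offsets(p, mrd$references)
  expect_equal(unname(sol$eps["1", ]), c(0, 0, 0))    # gauge reference
  tau <- global_bscan_coords(p, sol$eps, n_t = 3, n_y = n_y)
  expect_equal(mean(tau$x[tau$defined]), 0, tolerance = 1e-6)
  expect_equal(mean(tau$y[tau$defined]), 0, tolerance = 1e-6)
  expect_equal(mean(tau$z[tau$defined]), 0, tolerance = 1e-6)

  # adding a constant to all p of the non-gauge reference changes its offset
  # by the negative of the constant and leaves tau unchanged
  p_shift <- p
  p_shift$px[p_shift$R == 3] <- p_shift$px[p_shift$R == 3] + 5
  sol2 <- solve_reference_offsets(p_shift, mrd$references)
  expect_equal(sol2$eps["3", "x"], sol$eps["3", "x"] - 5, tolerance = 1e-9)
  tau2 <- global_bscan_coords(p_shift, sol2$eps, n_t = 3, n_y = n_y)
  expect_equal(tau2$x, tau$x, tolerance = 1e-9)
})

test_that("single motion-free target reduces tau to centered scanner positions", {
  n_y <- 12
  zero <- data.frame(i = 1:n_y, j = 1:n_y, dx = 0, dy = 0, dz = 0)
  mrd <- make_mrd(list("1" = list(zero)), n_y)
  p <- compute_p(mrd)
  sol <- solve_reference_offsets(p, mrd$references)
  tau <- global_bscan_coords(p, sol$eps, n_t = 1, n_y = n_y)
  expect_equal(tau$x, rep(0, n_y))
  expect_equal(tau$y, tau$i - mean(tau$i))
  expect_equal(tau$z, rep(0, n_y))
})

test_that("A-line coordinates follow chi = A (tau + sigma_alpha)", {
  tau <- data.frame(T = c(1, 1, 2), i = c(1, 2, 1),
                    x = c(0.5, -0.5, 2), y = c(-1, 0, 1), z = c(0, 1, -1),
                    n_refs = 1, defined = TRUE)
  n_x <- 5
  salpha <- 1:5 - 3
  # identity: chi = tau + sigma exactly
  chi <- aline_global_coords(tau, list(NULL, NULL), n_x)
  r1 <- chi[chi$T == 1 & chi$i == 1, ]
  expect_equal(r1$x, 0.5 + salpha)
  expect_equal(r1$y, rep(-1, 5))
  expect_equal(r1$z, rep(0, 5))

  # pure translation offsets every chi by (tx, ty, 0)
  A_t <- diag(3); A_t[1, 3] <- 3; A_t[2, 3] <- -2
  chi_t <- aline_global_coords(tau, list(A_t, A_t), n_x)
  expect_equal(chi_t$x, chi$x + 3)
  expect_equal(chi_t$y, chi$y - 2)
  expect_equal(chi_t$z, chi$z)

  # random affine against a per-A-line matrix-vector oracle
  set.seed(25)
  A_r <- diag(3); A_r[1:2, 1:2] <- matrix(stats::rnorm(4, sd = 0.3), 2) + diag(2)
  A_r[1:2, 3] <- stats::rnorm(2)
  chi_r <- aline_global_coords(tau, list(A_r, A_r), n_x)
  for (r in sample(nrow(chi_r), 5)) {
    row <- chi_r[r, ]
    t_row <- tau[tau$T == row$T & tau$i == row$i, ]
    v <- A_r %*% c(t_row$x + (row$alpha - 3), t_row$y, 1)
    expect_equal(c(row$x, row$y), as.numeric(v[1:2]), tolerance = 1e-12)
    expect_equal(row$z, t_row$z)
  }
})

test_that("identity rendering reproduces the input volume with unit counts", {
  v <- tiny_volume(n_y = 10)
  n_y <- 10; n_x <- dim(v$intensity)[2]
  tau <- data.frame(T = 1, i = 1:n_y, x = 0, y = (1:n_y) - (n_y + 1) / 2,
                    z = 0, n_refs = 1, defined = TRUE)
  chi <- aline_global_coords(tau, list(NULL), n_x)
  out <- render_global(list(v), chi)
  expect_equal(dim(out$volume$intensity), dim(v$intensity))
  expect_equal(out$volume$intensity, v$intensity, tolerance = 1e-12)
  expect_true(all(out$count == 1))
  # count conservation: total contributions = placed A-lines x depth pixels
  expect_equal(sum(out$count), n_y * n_x * dim(v$intensity)[1])
})

test_that("laterally offset volumes mosaic onto a larger canvas with overlap counts", {
  v <- tiny_volume(n_y = 10)
  n_y <- 10; n_x <- dim(v$intensity)[2]
  tau1 <- data.frame(T = 1, i = 1:n_y, x = 0, y = (1:n_y) - (n_y + 1) / 2,
                     z = 0, n_refs = 1, defined = TRUE)
  tau2 <- tau1; tau2$T <- 2; tau2$x <- 20   # shifted patch
  chi <- rbind(aline_global_coords(tau1, list(NULL, NULL), n_x),
               aline_global_coords(tau2, list(NULL, NULL), n_x))
  out <- render_global(list(v, v), chi)
  expect_equal(dim(out$volume$intensity)[2], n_x + 20)
  mid_counts <- out$count[1, , 5]
  expect_true(all(mid_counts[21:n_x] == 2))      # overlap
  expect_true(all(mid_counts[1:20] == 1))        # left flank
  expect_true(all(mid_counts[(n_x + 1):(n_x + 20)] == 1))  # right flank
  expect_error(render_global(list(v), chi[0, ]), "no A-line")
})

test_that("en-face similarity estimation recovers imposed rotations and scales", {
  ph <- small_phantom()
  g <- seq(8, 71, by = 1)
  sample_grid <- function(theta_deg, sf) {
    th <- theta_deg * pi / 180
    cx <- mean(g)
    outer(g, g, function(x, y) {
      u <- x - cx; w <- y - cx
      eval_phantom(ph, cx + sf * (cos(th) * u - sin(th) * w),
                   cx + sf * (sin(th) * u + cos(th) * w), 40)
    })
  }
  fixed <- sample_grid(0, 1)
  f0 <- estimate_affine(fixed, fixed)
  expect_equal(f0$rotation_deg, 0, tolerance = 0.02)
  expect_equal(f0$scale, 1, tolerance = 5e-4)

  f1 <- estimate_affine(sample_grid(1, 1), fixed)
  expect_equal(f1$rotation_deg, 1, tolerance = 0.1)

  f2 <- estimate_affine(sample_grid(0, 1.02), fixed)
  expect_equal(f2$scale, 1.02, tolerance = 0.005)

  f3 <- estimate_affine(sample_grid(-0.6, 0.99), fixed, model = "affine")
  expect_equal(f3$rotation_deg, -0.6, tolerance = 0.1)
  expect_equal(f3$scale, 0.99, tolerance = 0.005)
})
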