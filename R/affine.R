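# En-face affine (torsion/scale) estimation between videos.

# Bilinear sampling of image `img` (with logical mask) at real coordinates
# (r, c); returns list(values, valid).
bilinear_sample <- function(img, mask, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- r >= 1 & r <= nr - 1e-9 & c >= 1 & c <= nc - 1e-9
  val <- rep(NA_real_, length(r)); vok <- rep(FALSE, length(r))
  if (any(ok)) {
    r0 <- pmin(floor(r[ok]), nr - 1); c0 <- pmin(floor(c[ok]), nc - 1)
    wr <- r[ok] - r0; wc <- c[ok] - c0
    idx <- function(a, b) cbind(a, b)
    v <- img[idx(r0, c0)] * (1 - wr) * (1 - wc) +
      img[idx(r0 + 1, c0)] * wr * (1 - wc) +
      img[idx(r0, c0 + 1)] * (1 - wr) * wc +
      img[idx(r0 + 1, c0 + 1)] * wr * wc
    m <- mask[idx(r0, c0)] & mask[idx(r0 + 1, c0)] &
      mask[idx(r0, c0 + 1)] & mask[idx(r0 + 1, c0 + 1)]
    val[ok] <- v; vok[ok] <- m
  }
  list(values = val, valid = vok)
}

# Build the linear block L from a parameter vector.
affine_L <- function(par, model) {
  if (model == "similarity") {
    th <- par[1] * pi / 180; s <- exp(par[2])
    s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else if (model == "translation") {
    diag(2)
  } else {
    matrix(par[1:4], 2, 2)
  }
}

affine_t <- function(par, model) {
  switch(model, similarity = par[3:4], translation = par[1:2], par[5:6])
}

# Similarity between fixed and the moving image warped by (L, t) about
# center c0 (moving -> fixed: u = L (v - c0) + c0 + t). Returns a value to
# MINIMIZE.
affine_objective <- function(par, model, fixed, fmask, moving, mmask, c0,
                             metric) {
  L <- affine_L(par, model)
  dt <- det(L)
  if (!is.finite(dt) || dt <= 0.1 || dt > 10) return(1e6)
  Li <- solve(L)
  t <- affine_t(par, model)
  gr <- which(fmask, arr.ind = TRUE)
  # fixed pixel (row=x index, col=y index) -> centered coords
  ux <- gr[, 1] - c0[1]; uy <- gr[, 2] - c0[2]
  vx <- Li[1, 1] * (ux - t[1]) + Li[1, 2] * (uy - t[2]) + c0[1]
  vy <- Li[2, 1] * (ux - t[1]) + Li[2, 2] * (uy - t[2]) + c0[2]
  sm <- bilinear_sample(moving, mmask, vx, vy)
  sel <- sm$valid
  if (sum(sel) < 64) return(1e6)
  a <- fixed[gr[sel, , drop = FALSE]]
  b <- sm$values[sel]
  if (metric == "ncc") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1e6)
    -stats::cor(a, b)
  } else {
    -mutual_information(a, b)
  }
}

# Joint-histogram mutual information (nats), 32 bins.
mutual_information <- function(a, b, bins = 32) {
  qa <- pmin(bins, 1L + floor((a - min(a)) / diff(range(a)) * bins * 0.999999))
  qb <- pmin(bins, 1L + floor((b - min(b)) / diff(range(b)) * bins * 0.999999))
  jt <- table(factor(qa, 1:bins), factor(qb, 1:bins)) / length(a)
  pa <- rowSums(jt); pb <- colSums(jt)
  nzj <- jt > 0
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H(pa) + H(pb) - (-sum(jt[nzj] * log(jt[nzj])))
}

#' Estimate the en-face transform aligning one image to a reference
#'
#' Iteratively optimizes an image-similarity metric (masked normalized
#' cross-correlation by default, or joint-histogram mutual information) over
#' an en-face transform mapping the moving image into the fixed image frame.
#' The default `"similarity"` model (rotation + isotropic scale +
#' translation) matches the physical inter-video distortions — torsion and
#' magnification change; `"affine"` frees the full 2x2 linear block, which
#' can additionally represent shear at the cost of more variance.
#'
#' @param moving,fixed 2D images on a common grid (rows = x, cols = y).
#' @param moving_mask,fixed_mask logical coverage masks (default: all).
#' @param model `"similarity"` or `"affine"`.
#' @param metric `"ncc"` or `"mi"`.
#' @param center rotation/scale center `c(row, col)`; defaults to the grid
#'   center.
#' @param pre_smooth Gaussian sigma (px) applied to both images before
#'   optimization (0 = none).
#' @return list of class `enface_affine`: `A` (3x3 homogeneous matrix acting
#'   on centered `(x, y, 1)` coordinates), `rotation_deg` (`atan2(a21, a11)`),
#'   `scale` (`sqrt(det)` of the linear block), `similarity` (final metric),
#'   `converged`. On optimizer failure, identity with `converged = FALSE`.
#' @export
estimate_affine <- function(moving, fixed,
                            moving_mask = NULL, fixed_mask = NULL,
                            model = c("similarity", "affine", "translation"),
                            metric = c("ncc", "mi"),
                            center = NULL, pre_smooth = 1) {
  model <- match.arg(model); metric <- match.arg(metric)
  stopifnot(all(dim(moving) == dim(fixed)))
  if (is.null(moving_mask)) moving_mask <- array(TRUE, dim(moving))
  if (is.null(fixed_mask)) fixed_mask <- array(TRUE, dim(fixed))
  if (is.null(center)) center <- (dim(fixed) + 1) / 2
  if (pre_smooth > 0) {
    moving <- gauss_blur2d(moving, pre_smooth)
    fixed <- gauss_blur2d(fixed, pre_smooth)
  }

  # translation initialization from the masked-NCC peak: the cone mosaic is
  # quasi-periodic, so a gradient-free search starting at zero translation
  # can lock onto a lattice-aliased optimum
  mv0 <- moving; mv0[!moving_mask] <- 0
  fx0 <- fixed; fx0[!fixed_mask] <- 0
  pk <- ncc2d(mv0, fx0, min_overlap = 0.5)
  t0 <- c(-pk$dz, -pk$dx)
  par0 <- switch(model,
                 similarity = c(0, 0, t0),
                 translation = t0,
                 c(1, 0, 0, 1, t0))
  pscale <- switch(model,
                   similarity = c(0.2, 0.005, 0.5, 0.5),
                   translation = c(0.5, 0.5),
                   c(0.005, 0.005, 0.005, 0.005, 0.5, 0.5))
  obj <- function(par) affine_objective(par, model, fixed, fixed_mask,
                                        moving, moving_mask, center, metric)
  fit <- tryCatch({
    f1 <- stats::optim(par0, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12,
                                      parscale = pscale))
    stats::optim(f1$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-13,
                                parscale = pscale / 10))
  }, error = function(e) NULL)

  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e6) {
    return(structure(list(A = diag(3), rotation_deg = 0, scale = 1,
                          similarity = NA_real_, converged = FALSE,
                          model = model, metric = metric),
                     class = "enface_affine"))
  }
  L <- affine_L(fit$par, model)
  t <- affine_t(fit$par, model)
  # A acts on centered coordinates g (origin at `center`): g' = L g + t
  A <- diag(3)
  A[1:2, 1:2] <- L
  A[1:2, 3] <- t
  structure(list(A = A,
                 rotation_deg = atan2(L[2, 1], L[1, 1]) * 180 / pi,
                 scale = sqrt(abs(det(L))),
                 similarity = -fit$value, converged = fit$convergence == 0,
                 model = model, metric = metric),
            class = "enface_affine")
}

#' Per-video en-face subsets rendered from the B-scan global coordinates
#'
#' Averages, per video, the en-face rows of every defined B-scan of the
#' video's volumes placed at their tau coordinates on a common global
#' canvas; remaining slow-axis gaps are filled by linear interpolation along
#' y so the affine stage sees gap-free images.
#'
#' @param volumes list of [ao_volume()]s.
#' @param tau data.frame from [global_bscan_coords()].
#' @param video integer video id per volume.
#' @return list with `images` and `masks` (one per video, on a common
#'   canvas), `x0`, `y0` (global coordinate of canvas pixel (1,1)), and
#'   `center` (canvas coordinates of the global origin).
#' @export
video_enface_subsets <- function(volumes, tau, video) {
  n_x <- dim(volumes[[1]]$intensity)[2]
  salpha <- seq_len(n_x) - (n_x + 1) / 2
  td <- tau[tau$defined, , drop = FALSE]
  x0 <- min(round_half_up(td$x + min(salpha)))
  x1 <- max(round_half_up(td$x + max(salpha)))
  y0 <- min(round_half_up(td$y)); y1 <- max(round_half_up(td$y))
  nxo <- x1 - x0 + 1L; nyo <- y1 - y0 + 1L

  vids <- sort(unique(video))
  images <- list(); masks <- list()
  for (v in vids) {
    acc <- matrix(0, nxo, nyo); cnt <- matrix(0L, nxo, nyo)
    for (T in which(video == v)) {
      tv <- td[td$T == T, , drop = FALSE]
      ef <- apply(volumes[[T]]$intensity, c(2, 3), mean)  # x by y
      for (r in seq_len(nrow(tv))) {
        cols <- round_half_up(tv$x[r] + salpha) - x0 + 1L
        row <- round_half_up(tv$y[r]) - y0 + 1L
        okc <- cols >= 1L & cols <= nxo
        acc[cbind(cols[okc], row)] <- acc[cbind(cols[okc], row)] +
          ef[which(okc), tv$i[r]]
        cnt[cbind(cols[okc], row)] <- cnt[cbind(cols[okc], row)] + 1L
      }
    }
    img <- matrix(NA_real_, nxo, nyo)
    img[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    # fill slow-axis gaps between covered rows
    for (cx in seq_len(nxo)) {
      colv <- img[cx, ]
      obs <- which(!is.na(colv))
      if (length(obs) >= 2) {
        gap <- which(is.na(colv))
        inside <- gap[gap > min(obs) & gap < max(obs)]
        if (length(inside))
          img[cx, inside] <- stats::approx(obs, colv[obs], inside)$y
      }
    }
    masks[[as.character(v)]] <- !is.na(img)
    img[is.na(img)] <- 0
    images[[as.character(v)]] <- img
  }
  list(images = images, masks = masks, x0 = x0, y0 = y0,
       center = c(1 - x0, 1 - y0))  # canvas coords of global (0, 0)
}

#' Estimate per-volume en-face affines between videos
#'
#' Torsion and scale are constant within a video, so one en-face transform
#' is estimated per video and assigned to all its volumes. Each member
#' volume's en-face projection is registered (similarity model by default:
#' rotation, isotropic scale, translation) against the en-face projection
#' of the reference volume — the volume with the lowest variance in its
#' B-scan global coordinates — and the per-volume estimates are averaged
#' within the video (rotation angles and log scales), which reduces
#' estimator variance the way averaging the images would without the blur
#' that integer-precision registered averaging adds. En-face projections of
#' raw volumes keep the full torsion/scale signature: the B-scan stage's
#' per-B-scan x-shifts, which would partially absorb torsion, never touch
#' them.
#'
#' The per-volume matrices retain the estimated linear block but drop the
#' translation: the global solve already aligns the videos translationally
#' in the tau frame, whereas the estimated translation relates raw volume
#' frames.
#'
#' @param volumes list of [ao_volume()]s.
#' @param tau data.frame from [global_bscan_coords()].
#' @param video integer video id per volume.
#' @param mrd accepted for call compatibility; unused.
#' @param gate minimum median-similarity gain of the rotation/scale model
#'   over translation-only alignment for the correction to be applied. The
#'   default 0 only suppresses corrections that score worse than plain
#'   translation; raising it trades sensitivity to small torsions for
#'   robustness against fitting noise on torsion-free data (at this field
#'   size the two gain distributions overlap, so no default can separate
#'   them).
#' @param ... passed to [estimate_affine()] (e.g. `model`, `metric`).
#' @return list with `affines` (3x3 per volume; identity for the reference
#'   video), `fits` (per video: averaged `rotation_deg`, `scale`,
#'   `converged`, and the per-volume fits), `reference_video`,
#'   `reference_volume`.
#' @export
estimate_video_affines <- function(volumes, tau, video, mrd = NULL,
                                   gate = 0, ...) {
  n_y <- max(tau$i)
  td <- tau[tau$defined, , drop = FALSE]
  vvar <- vapply(seq_along(volumes), function(T) {
    tv <- td[td$T == T, , drop = FALSE]
    if (nrow(tv) < 3) return(Inf)
    stats::var(tv$x) + stats::var(tv$y - scanner_y(tv$i, n_y)) +
      stats::var(tv$z)
  }, numeric(1))
  ref_vol <- which.min(vvar)
  ref_vid <- video[ref_vol]

  enface <- function(T) apply(volumes[[T]]$intensity, c(2, 3), mean)
  ref_img <- enface(ref_vol)

  fits <- list()
  affines <- vector("list", length(volumes))
  for (v in sort(unique(video))) {
    k <- as.character(v)
    if (v == ref_vid) {
      fits[[k]] <- structure(list(A = diag(3), rotation_deg = 0, scale = 1,
                                  converged = TRUE, members = list()),
                             class = "enface_affine")
    } else {
      members <- which(video == v)
      mf <- lapply(members, function(T)
        estimate_affine(enface(T), ref_img, ...))
      # parsimony gate: a rotation/scale correction must beat plain
      # translation alignment by a clear similarity margin, otherwise the
      # extra degrees of freedom are fitting noise and a spurious
      # transform would degrade torsion-free data
      mt <- lapply(members, function(T)
        estimate_affine(enface(T), ref_img, model = "translation"))
      sim <- vapply(mf, function(f)
        if (is.finite(f$similarity)) f$similarity else -Inf, numeric(1))
      sim_t <- vapply(mt, function(f)
        if (is.finite(f$similarity)) f$similarity else -Inf, numeric(1))
      # a fit trapped in a lattice-aliased optimum scores visibly below the
      # well-aligned members: keep only fits close to the best similarity
      ok <- vapply(mf, `[[`, logical(1), "converged") &
        sim >= 0.9 * max(sim, na.rm = TRUE)
      gain <- stats::median(sim[ok]) - stats::median(sim_t[is.finite(sim_t)])
      if (!any(ok)) {
        fits[[k]] <- structure(list(A = diag(3), rotation_deg = 0, scale = 1,
                                    converged = FALSE, gain = NA_real_,
                                    members = mf),
                               class = "enface_affine")
      } else if (!is.finite(gain) || gain < gate) {
        fits[[k]] <- structure(list(A = diag(3), rotation_deg = 0, scale = 1,
                                    converged = TRUE, gain = gain,
                                    members = mf),
                               class = "enface_affine")
      } else {
        rot <- stats::median(vapply(mf[ok], `[[`, numeric(1), "rotation_deg"))
        scl <- exp(stats::median(log(vapply(mf[ok], `[[`, numeric(1),
                                            "scale"))))
        th <- rot * pi / 180
        A <- diag(3)
        A[1:2, 1:2] <- scl * matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                    2, 2)
        fits[[k]] <- structure(list(A = A, rotation_deg = rot, scale = scl,
                                    converged = TRUE, gain = gain,
                                    members = mf),
                               class = "enface_affine")
      }
    }
    A <- diag(3)
    if (fits[[k]]$converged) A[1:2, 1:2] <- fits[[k]]$A[1:2, 1:2]
    for (T in which(video == v)) affines[[T]] <- A
  }
  list(affines = affines, fits = fits, reference_video = ref_vid,
       reference_volume = ref_vol)
}
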