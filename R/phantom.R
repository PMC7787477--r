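#' Default retinal layer stack for the phantom
#'
#' Reflective outer-retinal bands emulating IS/OS, COST, ROST and RPE. Depth
#' centers and thicknesses (FWHM) are in micrometers; `brightness` scales the
#' band; `mosaic` bands carry the cone mosaic laterally, the others a smooth
#' speckle-free texture.
#'
#' @return a data.frame with one row per layer.
#' @export
default_layers <- function() {
  data.frame(
    name = c("ISOS", "COST", "ROST", "RPE"),
    depth = c(40, 58, 72, 88),
    thickness = c(6, 6, 7, 10),
    brightness = c(1.0, 0.85, 0.35, 0.5),
    mosaic = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build a cone-mosaic reflectance phantom
#'
#' The phantom is a continuous 3D reflectance field: a sum over retinal layers
#' of an axial Gaussian band profile times a lateral pattern. Photoreceptor
#' bands carry a jittered hexagonal lattice of Gaussian bright spots (the cone
#' mosaic); the remaining bands carry a smooth random texture. The lateral
#' patterns are rasterized once onto a fine grid and interpolated bilinearly,
#' so the field is defined at any real-valued coordinate; the axial profile is
#' evaluated analytically, making the overall interpolation trilinear-grade.
#'
#' The hexagonal lattice has nearest-neighbour spacing `cone_spacing`; its
#' dominant spectral ring (Yellott's ring) therefore sits at
#' [cone_peak_frequency()] `= 2 / (sqrt(3) * cone_spacing)` cycles/um.
#'
#' @param size extent in micrometers, named `c(x=, y=, z=)`.
#' @param cone_spacing center-to-center cone spacing in micrometers (> 0).
#' @param layers layer table as in [default_layers()].
#' @param mosaic_jitter SD of the random displacement of each cone center, um.
#' @param margin lateral margin (um) beyond `size` over which the field is
#'   defined, so that simulated eye motion can wander off the nominal patch.
#' @param grid_pitch rasterization pitch of the lateral patterns, um.
#' @param background additive background reflectance level.
#' @param seed integer; fixes the lattice jitter, per-cone brightness and
#'   texture exactly.
#' @return an object of class `ao_phantom`.
#' @export
build_phantom <- function(size = c(x = 120, y = 120, z = 120),
                          cone_spacing = 6,
                          layers = default_layers(),
                          mosaic_jitter = 0.8,
                          margin = 40,
                          grid_pitch = cone_spacing / 6,
                          background = 0.02,
                          seed = 1) {
  if (cone_spacing <= 0) stopf("cone_spacing must be > 0")
  size <- size[c("x", "y", "z")]
  if (any(is.na(size)) || any(size <= 0)) stopf("size must give positive x, y, z")
  if (size[["x"]] < 10 * cone_spacing || size[["y"]] < 10 * cone_spacing)
    stopf("field must contain at least a 10x10 cone patch")
  if (any(layers$depth < 0) || any(layers$depth > size[["z"]]))
    stopf("layer depth centers must lie inside the phantom depth extent")

  with_seed(seed, {
    x0 <- -margin; x1 <- size[["x"]] + margin
    y0 <- -margin; y1 <- size[["y"]] + margin
    gx <- seq(x0, x1, by = grid_pitch)
    gy <- seq(y0, y1, by = grid_pitch)

    # Jittered hexagonal lattice: rows sqrt(3)/2 * a apart, alternate rows
    # offset by a/2, nearest-neighbour distance = cone_spacing.
    a <- cone_spacing
    row_dy <- a * sqrt(3) / 2
    rows <- seq(y0, y1, by = row_dy)
    centers <- do.call(rbind, lapply(seq_along(rows), function(r) {
      xs <- seq(x0 + (r %% 2) * a / 2, x1, by = a)
      cbind(xs, rows[r])
    }))
    centers <- centers + matrix(stats::rnorm(2 * nrow(centers),
                                             sd = mosaic_jitter),
                                ncol = 2)
    amp <- stats::runif(nrow(centers), 0.75, 1.25)

    sigma <- a / 4
    mosaic <- matrix(0, length(gx), length(gy))
    half <- ceiling(3.5 * sigma / grid_pitch)
    for (k in seq_len(nrow(centers))) {
      cx <- centers[k, 1]; cy <- centers[k, 2]
      ix <- round((cx - x0) / grid_pitch) + 1L
      iy <- round((cy - y0) / grid_pitch) + 1L
      xs <- max(1L, ix - half):min(length(gx), ix + half)
      ys <- max(1L, iy - half):min(length(gy), iy + half)
      if (!length(xs) || !length(ys)) next
      gxk <- gx[xs] - cx; gyk <- gy[ys] - cy
      mosaic[xs, ys] <- mosaic[xs, ys] +
        amp[k] * exp(-outer(gxk^2, gyk^2, "+") / (2 * sigma^2))
    }

    # Smooth lateral texture for non-mosaic bands: Gaussian-filtered white
    # noise (correlation length ~ half the cone spacing), positive mean.
    tex <- matrix(stats::rnorm(length(gx) * length(gy)), length(gx))
    tex <- gauss_blur2d(tex, a / 2 / grid_pitch)
    tex <- 1 + 0.5 * tex / stats::sd(tex)
    tex[tex < 0] <- 0

    structure(list(size = size, cone_spacing = cone_spacing, layers = layers,
                   mosaic_jitter = mosaic_jitter, margin = margin,
                   grid_pitch = grid_pitch, background = background,
                   gx0 = x0, gy0 = y0, mosaic = mosaic, texture = tex,
                   centers = centers, seed = seed),
              class = "ao_phantom")
  })
}

#' @export
print.ao_phantom <- function(x, ...) {
  cat(sprintf(
    "ao_phantom: %g x %g x %g um, cone spacing %g um (%d cones), %d layers\n",
    x$size[["x"]], x$size[["y"]], x$size[["z"]], x$cone_spacing,
    nrow(x$centers), nrow(x$layers)))
  invisible(x)
}

#' Spatial frequency of the cone-mosaic spectral peak
#'
#' For a hexagonal mosaic with nearest-neighbour spacing `a`, the first ring
#' of the power spectrum (Yellott's ring) lies at `2 / (sqrt(3) * a)`
#' cycles/um, the reciprocal of the lattice row spacing.
#'
#' @param cone_spacing nearest-neighbour cone spacing, um.
#' @return frequency in cycles/um.
#' @export
cone_peak_frequency <- function(cone_spacing) 2 / (sqrt(3) * cone_spacing)

# Bilinear interpolation into a lateral grid (um coordinates), edge-clamped.
interp_lateral <- function(grid, x0, y0, pitch, x, y) {
  nx <- nrow(grid); ny <- ncol(grid)
  fx <- (x - x0) / pitch
  fy <- (y - y0) / pitch
  fx <- pmin(pmax(fx, 0), nx - 1 - 1e-9)
  fy <- pmin(pmax(fy, 0), ny - 1 - 1e-9)
  ix <- floor(fx); iy <- floor(fy)
  wx <- fx - ix; wy <- fy - iy
  i1 <- ix + 1L; j1 <- iy + 1L
  g <- function(i, j) grid[cbind(i, j)]
  g(i1, j1) * (1 - wx) * (1 - wy) + g(i1 + 1L, j1) * wx * (1 - wy) +
    g(i1, j1 + 1L) * (1 - wx) * wy + g(i1 + 1L, j1 + 1L) * wx * wy
}

# Axial band profile: Gaussian with FWHM = thickness.
axial_profile <- function(z, depth, thickness) {
  s <- thickness / (2 * sqrt(2 * log(2)))
  exp(-0.5 * ((z - depth) / s)^2)
}

#' Evaluate the phantom reflectance at arbitrary coordinates
#'
#' @param phantom an [build_phantom()] result.
#' @param x,y,z coordinate vectors in micrometers, recycled to equal length.
#' @return nonnegative reflectance values.
#' @export
eval_phantom <- function(phantom, x, y, z) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  out <- rep(phantom$background, n)
  mos <- NULL; tex <- NULL
  for (l in seq_len(nrow(phantom$layers))) {
    lay <- phantom$layers[l, ]
    ax <- axial_profile(z, lay$depth, lay$thickness)
    if (lay$mosaic) {
      if (is.null(mos))
        mos <- interp_lateral(phantom$mosaic, phantom$gx0, phantom$gy0,
                              phantom$grid_pitch, x, y)
      lat <- mos
    } else {
      if (is.null(tex))
        tex <- interp_lateral(phantom$texture, phantom$gx0, phantom$gy0,
                              phantom$grid_pitch, x, y)
      lat <- tex
    }
    out <- out + lay$brightness * ax * lat
  }
  out[out < 0] <- 0
  out
}

# FFT Gaussian blur of a matrix (sigma in pixels), circular boundary; used
# only for texture synthesis where wrap-around is harmless.
gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  H <- outer(exp(-2 * (pi * sigma * fr)^2), exp(-2 * (pi * sigma * fc)^2))
  Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (nr * nc)
}
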