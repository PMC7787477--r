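# Multi-reference global coordinate estimation.
#
# Displacement/coordinate sign conventions, used consistently everywhere:
# registration estimates Delta = target-minus-reference (dy = i - j, slot =
# i - dy, in-plane shift = -(dx, dz)). Under that convention the global
# (content-consistent) position of target B-scan (i, T) estimated through
# reference R is
#     p_{i,T;R} = a_{j;R} - Delta_d_{i,T;R} + s_i ,
# with a_{j;R} the reference's own per-B-scan mean displacement and
# s_i = (0, i - <i>, 0) the explicit scanner motion. p differs across
# references only by a per-reference constant, which the least-squares gauge
# solve estimates.

round_half_up <- function(x) floor(x + 0.5)

scanner_y <- function(i, n_y) i - (n_y + 1) / 2

#' Register every volume against multiple reference volumes
#'
#' Runs the coarse-to-fine B-scan registration for every (target, reference)
#' pair. A volume counts as registered to a reference when at least
#' `min_frac` of its B-scans survive the displacement filters. With
#' `references = "auto"`, the best-scoring volume ([select_reference()]) of
#' each video is used; if fewer than `target_frac` of volumes are registrable
#' to at least one reference, the next-best volumes from videos that still
#' contain unregistered volumes are promoted to references until the
#' criterion is met or candidates are exhausted.
#'
#' @param volumes list of pre-processed [ao_volume()]s.
#' @param video integer vector assigning each volume to a video.
#' @param references `"auto"` or integer indices into `volumes`.
#' @param min_frac fraction of included B-scans required to count a volume as
#'   registered to a reference.
#' @param target_frac global registrable fraction to reach before the
#'   automatic reference search stops (paper practice: 0.8).
#' @param ... registration controls passed to [register_bscans()].
#' @return a `multi_ref` object: per-pair displacement sets, the reference
#'   set, the T-by-R registered matrix and the global registrable fraction.
#' @export
multi_reference_register <- function(volumes, video = rep(1L, length(volumes)),
                                     references = "auto", min_frac = 0.5,
                                     target_frac = 0.8, ...) {
  n_t <- length(volumes)
  if (n_t == 0) stopf("no volumes supplied")
  stopifnot(length(video) == n_t)

  scores <- vapply(volumes, function(v) reference_quality_metric(v)$m,
                   numeric(1))
  auto <- identical(references, "auto")
  if (auto) {
    refs <- vapply(split(seq_len(n_t), video),
                   function(ix) ix[which.max(scores[ix])], integer(1))
    refs <- as.integer(refs)
  } else refs <- as.integer(references)

  pairs <- list()
  registered <- matrix(FALSE, n_t, 0)
  frac_included <- function(disp) {
    if (inherits(disp, "registration_failure")) return(0)
    mean(disp$displacements$included)
  }
  add_reference <- function(R) {
    col <- logical(n_t)
    pr <- vector("list", n_t)
    for (T in seq_len(n_t)) {
      disp <- register_bscans(volumes[[T]], volumes[[R]], ...)
      pr[[T]] <- disp
      col[T] <- frac_included(disp) >= min_frac
    }
    pairs[[as.character(R)]] <<- pr
    registered <<- cbind(registered, col)
    colnames(registered) <<- names(pairs)
  }
  for (R in refs) add_reference(R)

  frac <- mean(rowSums(registered) > 0)
  if (auto) {
    while (frac < target_frac) {
      unreg <- which(rowSums(registered) == 0)
      cand <- setdiff(order(scores, decreasing = TRUE), refs)
      cand <- cand[video[cand] %in% unique(video[unreg])]
      if (!length(cand)) break
      refs <- c(refs, cand[1])
      add_reference(cand[1])
      frac <- mean(rowSums(registered) > 0)
    }
  }

  structure(list(pairs = pairs, references = refs, registered = registered,
                 fraction = frac, video = video, scores = scores,
                 n_y = n_bscans(volumes[[1]]),
                 n_x = dim(volumes[[1]]$intensity)[2]),
            class = "multi_ref")
}

#' Per-B-scan motion estimate of a reference volume
#'
#' For each reference B-scan `j`, averages the displacements of all target
#' B-scans matched to it (`j = i - dy`) across target volumes; splits the
#' result into a constant `c_R` (mean over j) and a zero-mean part
#' `b = a - c_R`. Reference B-scans matched by no target are filled by linear
#' interpolation from their neighbours and flagged.
#'
#' @param mrd a `multi_ref` object.
#' @param R reference volume index (must be one of `mrd$references`).
#' @return list with `a` (n_y-by-3 matrix, columns x/y/z), `b`, `c_R`,
#'   `counts` and `observed` flags.
#' @export
reference_motion <- function(mrd, R) {
  stopifnot(inherits(mrd, "multi_ref"))
  key <- as.character(R)
  if (is.null(mrd$pairs[[key]])) stopf("volume %d is not a reference", R)
  n_y <- mrd$n_y
  acc <- matrix(0, n_y, 3); cnt <- integer(n_y)
  for (T in seq_len(length(mrd$pairs[[key]]))) {
    if (!mrd$registered[T, key]) next
    d <- mrd$pairs[[key]][[T]]$displacements
    d <- d[d$included, , drop = FALSE]
    for (r in seq_len(nrow(d))) {
      j <- d$j[r]
      acc[j, ] <- acc[j, ] + c(d$dx[r], d$dy[r], d$dz[r])
      cnt[j] <- cnt[j] + 1L
    }
  }
  observed <- cnt > 0
  if (sum(observed) < 2) stopf("reference %d has too few matched B-scans", R)
  a <- acc
  a[observed, ] <- acc[observed, ] / cnt[observed]
  for (ax in 1:3)
    a[!observed, ax] <- lin_interp_extrap(which(observed), a[observed, ax],
                                          which(!observed))
  c_R <- colMeans(a)
  list(a = a, b = sweep(a, 2, c_R), c_R = c_R, counts = cnt,
       observed = observed)
}

#' Reference-corrected global position estimates p
#'
#' For every included B-scan of every (target, reference) pairing, computes
#' `p = a_{j;R} - Delta_d + s_i` (see the convention note in this module):
#' the B-scan's estimated global position, up to a per-reference constant.
#'
#' @param mrd a `multi_ref` object.
#' @param motions optional named list of [reference_motion()] results keyed
#'   by reference index (computed when missing).
#' @return long data.frame `T, i, R, px, py, pz`.
#' @export
compute_p <- function(mrd, motions = NULL) {
  stopifnot(inherits(mrd, "multi_ref"))
  if (is.null(motions)) {
    motions <- lapply(mrd$references, function(R) reference_motion(mrd, R))
    names(motions) <- as.character(mrd$references)
  }
  n_y <- mrd$n_y
  rows <- list()
  for (R in mrd$references) {
    key <- as.character(R)
    a <- motions[[key]]$a
    for (T in seq_len(nrow(mrd$registered))) {
      if (!mrd$registered[T, key]) next
      d <- mrd$pairs[[key]][[T]]$displacements
      d <- d[d$included, , drop = FALSE]
      if (!nrow(d)) next
      j <- d$j
      rows[[length(rows) + 1L]] <- data.frame(
        T = T, i = d$i, R = R,
        px = a[j, 1] - d$dx,
        py = a[j, 2] - d$dy + scanner_y(d$i, n_y),
        pz = a[j, 3] - d$dz)
    }
  }
  if (!length(rows)) stopf("no registered B-scans; cannot compute p")
  do.call(rbind, rows)
}

#' Solve the per-reference offsets by exact least squares
#'
#' Minimizes, independently per axis, the sum over reference pairs (R, R')
#' of the squared differences `(p_R + e_R) - (p_R' + e_R')` over the B-scans
#' registered to both, with the gauge `e_{R0} = 0` for the first reference.
#' The quadratic cost has a closed-form minimizer: a graph-Laplacian linear
#' system over the reference-overlap graph, solved per connected component
#' (disconnected components are gauged separately with a warning).
#'
#' @param p data.frame from [compute_p()].
#' @param references reference indices (defaults to those present in `p`).
#' @return list with `eps` (n_ref-by-3 matrix of offsets, rows named by
#'   reference) and `components` (component id per reference).
#' @export
solve_reference_offsets <- function(p, references = sort(unique(p$R))) {
  nR <- length(references)
  eps <- matrix(0, nR, 3,
                dimnames = list(as.character(references), c("x", "y", "z")))
  if (nR == 1) return(list(eps = eps, components = 1L))

  key <- function(T, i) paste(T, i)
  obs <- split(seq_len(nrow(p)), p$R)
  L <- matrix(0, nR, nR)
  rhs <- matrix(0, nR, 3)
  for (r1 in seq_len(nR - 1)) {
    for (r2 in (r1 + 1):nR) {
      i1 <- obs[[as.character(references[r1])]]
      i2 <- obs[[as.character(references[r2])]]
      if (is.null(i1) || is.null(i2)) next
      k1 <- key(p$T[i1], p$i[i1]); k2 <- key(p$T[i2], p$i[i2])
      m <- match(k1, k2)
      sh <- which(!is.na(m))
      if (!length(sh)) next
      a <- i1[sh]; b <- i2[m[sh]]
      n_w <- length(sh)
      dsum <- c(sum(p$px[a] - p$px[b]), sum(p$py[a] - p$py[b]),
                sum(p$pz[a] - p$pz[b]))
      L[r1, r1] <- L[r1, r1] + n_w
      L[r2, r2] <- L[r2, r2] + n_w
      L[r1, r2] <- L[r1, r2] - n_w
      L[r2, r1] <- L[r2, r1] - n_w
      rhs[r1, ] <- rhs[r1, ] - dsum
      rhs[r2, ] <- rhs[r2, ] + dsum
    }
  }

  # connected components of the overlap graph
  adj <- L != 0; diag(adj) <- TRUE
  comp <- rep(0L, nR); cid <- 0L
  for (r in seq_len(nR)) {
    if (comp[r] > 0L) next
    cid <- cid + 1L
    frontier <- r
    while (length(frontier)) {
      comp[frontier] <- cid
      nxt <- unique(unlist(lapply(frontier, function(q) which(adj[q, ]))))
      frontier <- setdiff(nxt[comp[nxt] == 0L], frontier)
    }
  }
  if (cid > 1)
    warnf("reference overlap graph has %d components; gauging each separately",
          cid)

  for (cc in seq_len(cid)) {
    mem <- which(comp == cc)
    if (length(mem) < 2) next
    gauge <- mem[1]
    free <- setdiff(mem, gauge)
    sol <- solve(L[free, free, drop = FALSE], rhs[free, , drop = FALSE])
    eps[free, ] <- sol
  }
  list(eps = eps, components = comp)
}

#' Global B-scan coordinates tau
#'
#' Averages `p + eps_R` over the references each B-scan is registered to,
#' then removes the grand mean so the ensemble of B-scan coordinates is
#' zero-mean in all three axes. B-scans registered to no reference are
#' reported undefined.
#'
#' @param p data.frame from [compute_p()].
#' @param eps offset matrix from [solve_reference_offsets()].
#' @param n_t,n_y full grid extents (targets, B-scans per volume).
#' @return data.frame `T, i, x, y, z, n_refs, defined` covering the full
#'   (T, i) grid.
#' @export
global_bscan_coords <- function(p, eps, n_t = max(p$T), n_y = max(p$i)) {
  ek <- as.character(p$R)
  px <- p$px + eps[ek, "x"]
  py <- p$py + eps[ek, "y"]
  pz <- p$pz + eps[ek, "z"]
  g <- interaction(p$T, p$i, drop = TRUE)
  ox <- tapply(px, g, mean); oy <- tapply(py, g, mean); oz <- tapply(pz, g, mean)
  nref <- tapply(px, g, length)
  ids <- do.call(rbind, strsplit(names(ox), "\\."))
  Tg <- as.integer(ids[, 1]); ig <- as.integer(ids[, 2])

  out <- expand.grid(i = seq_len(n_y), T = seq_len(n_t))[, c("T", "i")]
  out$x <- NA_real_; out$y <- NA_real_; out$z <- NA_real_
  out$n_refs <- 0L; out$defined <- FALSE
  at <- match(paste(Tg, ig), paste(out$T, out$i))
  out$x[at] <- ox; out$y[at] <- oy; out$z[at] <- oz
  out$n_refs[at] <- as.integer(nref); out$defined[at] <- TRUE

  mx <- mean(out$x[out$defined]); my <- mean(out$y[out$defined])
  mz <- mean(out$z[out$defined])
  out$x <- out$x - mx; out$y <- out$y - my; out$z <- out$z - mz
  out
}

#' A-line global coordinates chi
#'
#' Applies each volume's en-face affine to its B-scan coordinates plus the
#' explicit fast-axis scanner term: `chi = A_T (tau + sigma_alpha)` with
#' `sigma_alpha = (alpha - <alpha>, 0, 0)`, depth passed through unchanged.
#'
#' @param tau data.frame from [global_bscan_coords()].
#' @param affines list (indexed by volume T) of 3x3 en-face matrices acting
#'   on global `(x, y, 1)` coordinates, or `NULL` entries for identity.
#' @param n_x A-lines per B-scan.
#' @return data.frame `T, i, alpha, x, y, z` for every defined B-scan.
#' @export
aline_global_coords <- function(tau, affines, n_x) {
  tau <- tau[tau$defined, , drop = FALSE]
  alpha <- seq_len(n_x)
  salpha <- alpha - mean(alpha)
  rows <- vector("list", nrow(tau))
  for (r in seq_len(nrow(tau))) {
    A <- affines[[tau$T[r]]]
    X <- tau$x[r] + salpha
    Y <- rep(tau$y[r], n_x)
    if (!is.null(A)) {
      Xn <- A[1, 1] * X + A[1, 2] * Y + A[1, 3]
      Y  <- A[2, 1] * X + A[2, 2] * Y + A[2, 3]
      X <- Xn
    }
    rows[[r]] <- data.frame(T = tau$T[r], i = tau$i[r], alpha = alpha,
                            x = X, y = Y, z = tau$z[r])
  }
  do.call(rbind, rows)
}

#' Render the globally averaged volume
#'
#' Splats each A-line of every defined B-scan to the nearest voxel column of
#' a global grid at `round(chi)` (depth shifted by the rounded z
#' coordinate), accumulating sums and counts; the output voxel value is the
#' mean of all contributions. The grid auto-expands to the bounding box of
#' the coordinates, which is what extends the field of view beyond a single
#' volume; the same machinery averages focus stacks.
#'
#' @param volumes list of [ao_volume()]s (common shape).
#' @param chi data.frame from [aline_global_coords()].
#' @param grid `"auto"` or a list with `x0, x1, y0, y1, z0, z1` (global
#'   coordinates, inclusive).
#' @return list with `volume` (averaged [ao_volume()] on the grid), `count`
#'   (3D contribution counts) and `grid` (the origin/extents used).
#' @export
render_global <- function(volumes, chi, grid = "auto") {
  if (!nrow(chi)) stopf("no A-line coordinates to render")
  n_z <- dim(volumes[[1]]$intensity)[1]
  cx <- round_half_up(chi$x); cy <- round_half_up(chi$y)
  cz <- round_half_up(chi$z)
  if (identical(grid, "auto")) {
    grid <- list(x0 = min(cx), x1 = max(cx), y0 = min(cy), y1 = max(cy),
                 z0 = min(cz), z1 = max(cz))
  }
  nx_out <- grid$x1 - grid$x0 + 1L
  ny_out <- grid$y1 - grid$y0 + 1L
  nz_out <- n_z + (grid$z1 - grid$z0)
  acc <- array(0, dim = c(nz_out, nx_out, ny_out))
  cnt <- array(0L, dim = c(nz_out, nx_out, ny_out))

  col <- cx - grid$x0 + 1L
  row <- cy - grid$y0 + 1L
  zoff <- cz - grid$z0
  inside <- col >= 1L & col <= nx_out & row >= 1L & row <= ny_out
  zs <- seq_len(n_z)
  for (r in which(inside)) {
    aline <- volumes[[chi$T[r]]]$intensity[, chi$alpha[r], chi$i[r]]
    zi <- zs + zoff[r]
    acc[zi, col[r], row[r]] <- acc[zi, col[r], row[r]] + aline
    cnt[zi, col[r], row[r]] <- cnt[zi, col[r], row[r]] + 1L
  }
  nz <- cnt > 0
  acc[nz] <- acc[nz] / cnt[nz]
  vol <- ao_volume(acc, pitch = volumes[[1]]$pitch,
                   bscan_rate = volumes[[1]]$bscan_rate,
                   id = list(video = NA, volume = NA))
  list(volume = vol, count = cnt, grid = grid)
}

#' Coverage-aware en-face projection of a rendered global average
#'
#' The global grid's depth extent exceeds a single volume's, so some voxels
#' of every A-line column are never covered; a plain mean over z would
#' modulate the image with the per-column covered fraction. This projection
#' averages only covered voxels per (x, y) column.
#'
#' @param render a [render_global()] result.
#' @return an `enface_image` matrix (x by y); columns with no coverage are
#'   `NA`.
#' @export
render_enface <- function(render) {
  covered <- render$count > 0
  num <- apply(render$volume$intensity * covered, c(2, 3), sum)
  den <- apply(covered, c(2, 3), sum)
  img <- num / ifelse(den > 0, den, NA)
  structure(img, pitch = unname(render$volume$pitch[c("x", "y")]),
            class = c("enface_image", "matrix", "array"))
}
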