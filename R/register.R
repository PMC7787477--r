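#' Coarse displacement trace between two volumes via 3D POC
#'
#' Sub-volumes of `2 * d` contiguous fast B-scans, centered every `s` B-scans
#' along the slow axis, are each registered rigidly to the reference volume
#' with 3D phase-only correlation. Samples whose POC failed, or whose y
#' displacement jumps by more than `s` relative to both neighbouring samples
#' (one neighbour at the trace ends), are flagged invalid: they deviate from
#' the overall motion trend. Edge samples whose window is clipped by the
#' volume boundary are used but flagged `truncated`.
#'
#' @param target,reference pre-processed [ao_volume()]s with a common B-scan
#'   shape.
#' @param s sampling interval in B-scans (default 15; useful range 5-30).
#' @param d sample half-width in B-scans (default 6; `2d` in 8-16).
#' @param overlap logical: halve the effective spacing so sample sub-volumes
#'   overlap (robustness to large, rapid eye movements).
#' @return a `coarse_trace` object: data.frame of sample centers and
#'   displacements plus an `ok` flag (`FALSE` when fewer than 2 samples are
#'   valid, i.e. the volume is unregistrable to this reference).
#' @export
coarse_trace <- function(target, reference, s = 15, d = 6, overlap = FALSE) {
  stopifnot(inherits(target, "ao_volume"), inherits(reference, "ao_volume"))
  if (!all(dim(target$intensity)[1:2] == dim(reference$intensity)[1:2]))
    stopf("target and reference must share the B-scan (z, x) shape")
  if (s <= 0 || d <= 0) stopf("s and d must be > 0")
  step <- if (overlap) max(1L, as.integer(round(s / 2))) else as.integer(s)
  n_y <- n_bscans(target)
  centers <- seq(step, n_y, by = step)
  if (!length(centers)) centers <- as.integer(round(n_y / 2))

  prep <- poc_prepare_reference(reference$intensity, d)
  rows_lo <- pmax(1L, centers - as.integer(d) + 1L)
  rows_hi <- pmin(n_y, centers + as.integer(d))
  truncated <- (rows_hi - rows_lo + 1L) < 2L * d

  res <- lapply(seq_along(centers), function(k) {
    sub <- target$intensity[, , rows_lo[k]:rows_hi[k], drop = FALSE]
    poc3d(sub, prep, y_start = rows_lo[k], d = d)
  })
  df <- data.frame(
    sample = seq_along(centers), center = centers,
    dX = vapply(res, `[[`, numeric(1), "dx"),
    dY = vapply(res, `[[`, numeric(1), "dy"),
    dZ = vapply(res, `[[`, numeric(1), "dz"),
    peak = vapply(res, `[[`, numeric(1), "peak"),
    truncated = truncated,
    valid = vapply(res, `[[`, logical(1), "valid"))

  # Trend filter among POC-valid samples, two passes: interior samples that
  # jump by more than s relative to both neighbours are outliers; then edge
  # samples are peeled off while they jump by more than s relative to the
  # nearest surviving sample (an interior outlier must not condemn its edge
  # neighbour).
  vi <- which(df$valid)
  if (length(vi) >= 3)
    df$valid[vi[!trend_keep(df$dY[vi], s)]] <- FALSE

  structure(list(samples = df, s = s, d = d, n_y = n_y,
                 ok = sum(df$valid) >= 2),
            class = "coarse_trace")
}

# Trend rule on a vector of coarse dY estimates: returns a logical keep
# mask. Interior samples jumping by more than s relative to both neighbours
# are dropped; then edge samples are peeled while they jump by more than s
# relative to the nearest survivor.
trend_keep <- function(dy, s) {
  nv <- length(dy)
  jump_prev <- c(FALSE, abs(diff(dy)) > s)
  jump_next <- c(abs(diff(dy)) > s, FALSE)
  keep <- !(seq_len(nv) > 1 & seq_len(nv) < nv & jump_prev & jump_next)
  surv <- which(keep)
  while (length(surv) >= 2 && abs(dy[surv[1]] - dy[surv[2]]) > s)
    surv <- surv[-1]
  while (length(surv) >= 2 &&
         abs(dy[surv[length(surv)]] - dy[surv[length(surv) - 1]]) > s)
    surv <- surv[-length(surv)]
  seq_len(nv) %in% surv
}

#' Predict per-B-scan slow-axis positions from a coarse trace
#'
#' Up-samples the valid coarse y displacements with a linear interpolator to
#' every B-scan index `i`; B-scans beyond the outermost valid samples are
#' linearly extrapolated from the nearest pair. The predicted position of
#' B-scan `i` in the reference is `y_pred = i - dy_pred`.
#'
#' @param trace a [coarse_trace()] with `ok = TRUE`.
#' @param n_bscans number of B-scans to predict (defaults to the trace's).
#' @return data.frame with `i`, `dy_pred`, `y_pred`.
#' @export
predict_positions <- function(trace, n_bscans = trace$n_y) {
  stopifnot(inherits(trace, "coarse_trace"))
  if (!trace$ok)
    stopf("coarse trace has fewer than 2 valid samples; volume unregistrable")
  v <- trace$samples[trace$samples$valid, ]
  i <- seq_len(n_bscans)
  dy <- lin_interp_extrap(v$center, v$dY, i)
  data.frame(i = i, dy_pred = dy, y_pred = i - dy)
}

#' Fine per-B-scan registration with overlap-normalized cross-correlation
#'
#' Each target fast B-scan `i` is correlated (2D masked NCC over the full
#' z-x extent) against every reference B-scan `j` within
#' `round(y_pred_i) +/- w_y`; the displacement is the global argmax over all
#' candidates: `(dz, dx)` from the NCC peak and `dy = i - j*`. Registration
#' is pixel-level (no sub-pixel refinement). B-scans whose search window
#' falls entirely outside the reference are marked unmatched.
#'
#' @param target,reference [ao_volume()]s with a common B-scan shape.
#' @param predictions data.frame from [predict_positions()].
#' @param w_y search half-width in B-scans (default 8, i.e. 17 candidates).
#' @param min_overlap minimum in-plane overlap fraction for an NCC offset.
#' @return a `bscan_displacements` object: data.frame `i, j, dx, dy, dz, ncc,
#'   y_pred, matched` plus acquisition metadata.
#' @export
ncc_fine <- function(target, reference, predictions, w_y = 8,
                     min_overlap = 0.5) {
  stopifnot(inherits(target, "ao_volume"), inherits(reference, "ao_volume"))
  if (w_y < 1) stopf("w_y must be >= 1")
  dt <- dim(target$intensity); dr <- dim(reference$intensity)
  if (!all(dt[1:2] == dr[1:2]))
    stopf("target and reference must share the B-scan (z, x) shape")
  n_y <- dt[3]; n_yr <- dr[3]
  stopifnot(nrow(predictions) == n_y)

  geom <- ncc_geometry(dt[1], dt[2], min_overlap)
  t_cache <- vector("list", n_yr)

  out <- data.frame(i = seq_len(n_y), j = NA_integer_,
                    dx = NA_real_, dy = NA_real_, dz = NA_real_,
                    ncc = NA_real_, y_pred = predictions$y_pred,
                    matched = FALSE)
  for (i in seq_len(n_y)) {
    jc <- round(predictions$y_pred[i])
    # a prediction slightly outside the reference is clamped to the edge
    # (coarse extrapolation is least reliable there); far outside -> unmatched
    if (jc < 1L - 2L * w_y || jc > n_yr + 2L * w_y) next
    jc <- min(max(jc, 1L), n_yr)
    js <- max(1L, jc - w_y):min(n_yr, jc + w_y)
    pf <- ncc_prep_f(target$intensity[, , i], geom)
    best <- list(rho = -Inf)
    for (j in js) {
      if (is.null(t_cache[[j]]))
        t_cache[[j]] <- ncc_prep_t(reference$intensity[, , j], geom)
      pk <- ncc_peak(ncc_map(pf, t_cache[[j]], geom), geom)
      if (pk$rho > best$rho) best <- c(pk, list(j = j))
    }
    if (!is.finite(best$rho)) next
    out$j[i] <- best$j
    out$dx[i] <- best$dx
    out$dy[i] <- i - best$j
    out$dz[i] <- best$dz
    out$ncc[i] <- best$rho
    out$matched[i] <- TRUE
  }
  structure(list(displacements = out, w_y = w_y,
                 bscan_rate = target$bscan_rate,
                 target_id = target$id, reference_id = reference$id),
            class = "bscan_displacements")
}

#' Exclude outlying or low-confidence B-scan displacements
#'
#' A B-scan is excluded when the local standard deviation of displacements
#' within a `window_ms` window centered on it (converted to B-scans through
#' the B-scan rate, minimum 5) exceeds `sigma_max_px` on any axis, or when
#' its NCC coefficient falls below `ncc_min`. Unmatched B-scans stay
#' excluded.
#'
#' @param disp a `bscan_displacements` from [ncc_fine()].
#' @param window_ms outlier window in milliseconds (~20 ms).
#' @param sigma_max_px local displacement SD threshold in pixels (3-5).
#' @param ncc_min minimum NCC coefficient (default 0.3).
#' @return the object with `included` and `sigma_delta` columns added.
#' @export
filter_outliers <- function(disp, window_ms = 20, sigma_max_px = 4,
                            ncc_min = 0.3) {
  stopifnot(inherits(disp, "bscan_displacements"))
  d <- disp$displacements
  n <- nrow(d)
  w <- max(5L, as.integer(round(window_ms / 1000 * disp$bscan_rate)))
  h <- w %/% 2L
  sig <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- max(1L, i - h):min(n, i + h)
    win <- win[d$matched[win]]
    if (length(win) >= 2) {
      sig[i] <- max(stats::sd(d$dx[win]), stats::sd(d$dy[win]),
                    stats::sd(d$dz[win]))
    } else sig[i] <- 0
  }
  d$sigma_delta <- sig
  d$included <- d$matched & d$ncc >= ncc_min & sig <= sigma_max_px
  disp$displacements <- d
  disp$filter <- list(window_ms = window_ms, window_bscans = w,
                      sigma_max_px = sigma_max_px, ncc_min = ncc_min)
  disp
}

#' Register one target volume to a reference (coarse-to-fine)
#'
#' Convenience cascade: [coarse_trace()] then [predict_positions()] then
#' [ncc_fine()] then [filter_outliers()].
#'
#' @param target,reference pre-processed [ao_volume()]s.
#' @param s,d,overlap coarse sampling controls, see [coarse_trace()].
#' @param w_y fine search half-width, see [ncc_fine()].
#' @param window_ms,sigma_max_px,ncc_min outlier controls, see
#'   [filter_outliers()].
#' @param min_overlap NCC overlap floor.
#' @return a filtered `bscan_displacements`, or a `registration_failure`
#'   object when the coarse stage finds fewer than 2 valid samples.
#' @export
register_bscans <- function(target, reference, s = 15, d = 6, w_y = 8,
                            overlap = FALSE, window_ms = 20,
                            sigma_max_px = 4, ncc_min = 0.3,
                            min_overlap = 0.5) {
  ct <- coarse_trace(target, reference, s = s, d = d, overlap = overlap)
  if (!ct$ok)
    return(structure(list(ok = FALSE, target_id = target$id,
                          reference_id = reference$id),
                     class = "registration_failure"))
  pred <- predict_positions(ct, n_bscans = n_bscans(target))
  disp <- ncc_fine(target, reference, pred, w_y = w_y,
                   min_overlap = min_overlap)
  disp$coarse <- ct
  filter_outliers(disp, window_ms = window_ms, sigma_max_px = sigma_max_px,
                  ncc_min = ncc_min)
}

#' Construct a registered volume from filtered displacements
#'
#' Every included target B-scan `i` is placed at slow-axis slot `i - dy_i`
#' and shifted in-plane by `(-dx_i, -dz_i)` (integer shifts, zero fill).
#' When several B-scans land on the same slot the last acquired one wins;
#' slots receiving no B-scan are flagged in the gap mask. Placements falling
#' outside `[1, n_y]` are dropped and counted.
#'
#' @param target the target [ao_volume()].
#' @param disp filtered `bscan_displacements` for this target.
#' @return list with `volume` (registered [ao_volume()]), `gap_mask` (logical
#'   per slot) and `report` (placed/excluded/collided/dropped/gap counts;
#'   `placed + gaps == n_y` always).
#' @export
construct_registered <- function(target, disp) {
  stopifnot(inherits(target, "ao_volume"),
            inherits(disp, "bscan_displacements"))
  d <- disp$displacements
  if (is.null(d$included)) stopf("displacements must be filtered first")
  n_y <- n_bscans(target)
  if (!any(d$included)) {
    return(structure(list(volume = NULL, gap_mask = rep(TRUE, n_y),
                          report = list(placed = 0L, excluded = n_y,
                                        collided = 0L, dropped = 0L,
                                        gaps = n_y, empty = TRUE)),
                     class = "registered_volume"))
  }
  out <- array(0, dim = dim(target$intensity))
  filled <- rep(FALSE, n_y)
  collided <- 0L; dropped <- 0L
  for (i in seq_len(n_y)) {           # ascending i: last acquired wins
    if (!d$included[i]) next
    slot <- i - as.integer(d$dy[i])
    if (slot < 1L || slot > n_y) { dropped <- dropped + 1L; next }
    if (filled[slot]) collided <- collided + 1L
    out[, , slot] <- shift_matrix(target$intensity[, , i],
                                  as.integer(d$dz[i]), as.integer(d$dx[i]))
    filled[slot] <- TRUE
  }
  vol <- target
  vol$intensity <- out
  structure(list(volume = vol, gap_mask = !filled,
                 report = list(placed = sum(filled),
                               excluded = sum(!d$included),
                               collided = collided, dropped = dropped,
                               gaps = sum(!filled), empty = FALSE)),
            class = "registered_volume")
}

#' Average registered volumes, ignoring gaps
#'
#' Per-voxel mean over the volumes whose gap mask is clear at that slot; the
#' per-slot count map is returned and zero-count slots flagged.
#'
#' @param registered list of [construct_registered()] results (common shape).
#' @return list with `volume` (mean [ao_volume()]), `count` (per-slot
#'   contributions) and `uncovered` (slots with zero contributions).
#' @export
average_registered <- function(registered) {
  registered <- Filter(function(r) !r$report$empty, registered)
  if (!length(registered)) stopf("no non-empty registered volumes to average")
  tmpl <- registered[[1]]$volume
  n_y <- n_bscans(tmpl)
  acc <- array(0, dim = dim(tmpl$intensity))
  count <- integer(n_y)
  for (r in registered) {
    ok <- !r$gap_mask
    acc[, , ok] <- acc[, , ok] + r$volume$intensity[, , ok]
    count[ok] <- count[ok] + 1L
  }
  nz <- count > 0
  for (slot in which(nz)) acc[, , slot] <- acc[, , slot] / count[slot]
  out <- tmpl
  out$intensity <- acc
  list(volume = out, count = count, uncovered = which(!nz))
}
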