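# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Smallest power of two not smaller than `n`
#' @param n positive integer.
#' @return integer power of two `>= n`.
#' @keywords internal
next_pow2 <- function(n) {
  stopifnot(n >= 1)
  as.integer(2^ceiling(log2(n)))
}

# Smallest multiple of `m` that is >= n.
next_multiple <- function(n, m) as.integer(m * ceiling(n / m))

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n; keeps mixed-radix FFTs fast.
next_fast_size <- function(n) {
  stopifnot(n >= 1)
  k <- as.integer(n)
  repeat {
    m <- k
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(k)
    k <- k + 1L
  }
}

# Decode a 1-based circular index on an axis of length `n` into a signed
# shift in [-n/2, n/2).
decode_shift <- function(idx, n) {
  s <- idx - 1L
  ifelse(s >= n / 2, s - n, s)
}

# Zero-pad a 3D array to `dims`, placing the input at offset `at` (1-based).
pad_embed <- function(x, dims, at = c(1L, 1L, 1L)) {
  out <- array(0, dim = dims)
  d <- dim(x)
  out[at[1]:(at[1] + d[1] - 1L),
      at[2]:(at[2] + d[2] - 1L),
      at[3]:(at[3] + d[3] - 1L)] <- x
  out
}

# Integer in-plane shift of a matrix with zero fill: out[r, c] = x[r + dr, c + dc].
shift_matrix <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) + dr
  src_c <- seq_len(nc) + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- x[src_r[ok_r], src_c[ok_c]]
  out
}

# Linear interpolation/extrapolation of (xs, ys) at xout; extrapolates from
# the nearest pair at both ends (stats::approx only holds values constant).
lin_interp_extrap <- function(xs, ys, xout) {
  stopifnot(length(xs) == length(ys), length(xs) >= 2)
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  out <- stats::approx(xs, ys, xout, rule = 2)$y
  n <- length(xs)
  lo <- xout < xs[1]
  if (any(lo)) {
    sl <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[lo] <- ys[1] + sl * (xout[lo] - xs[1])
  }
  hi <- xout > xs[n]
  if (any(hi)) {
    sl <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[hi] <- ys[n] + sl * (xout[hi] - xs[n])
  }
  out
}
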