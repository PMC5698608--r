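# Undecimated (a trous) quadratic spline wavelet transform. The wavelet acts
# as a smoothed derivative: a systolic upstroke/downstroke produces an
# opposite-sign pair of modulus maxima whose zero-crossing marks the apex —
# the mechanism the peak detector exploits.

#' Quadratic spline wavelet filter bank
#'
#' The Mallat-Zhong pair: lowpass `h = (0.125, 0.375, 0.375, 0.125)` (a
#' B-spline smoother, sums to 1) and highpass `g = (2, -2)` (a first
#' difference, sums to 0 so constants are annihilated). The detector is
#' invariant to any per-level rescaling of these taps because its threshold is
#' data-adaptive.
#'
#' @return list with numeric `h` and `g`.
#' @export
qspline_filters <- function() {
  list(h = c(0.125, 0.375, 0.375, 0.125), g = c(2, -2))
}

# Half-point symmetric extension index map: fold any integer index (possibly
# <1 or >n) into [1, n]; period 2n, boundary sample duplicated.
.sym_index <- function(idx, n) {
  m <- (idx - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Group delay (in samples) of the cascade up to detail level i, given causal
# taps h at lags 0..3 (delay 1.5 per pass, scaled by the a trous step) and g
# at lags 0..1 (delay 0.5). Compensated by shifting each output left.
.qspline_delay <- function(i) {
  1.5 * (2^(i - 1) - 1) + 0.5 * 2^(i - 1)
}

#' Undecimated quadratic spline wavelet decomposition
#'
#' Computes detail coefficient series `W1..WL` (and the final approximation),
#' all at full signal length, by the a trous scheme: at level *i* the level
#' *(i-1)* approximation is filtered with `h` and `g` carrying `2^(i-1) - 1`
#' zeros between taps. Boundaries use half-point symmetric extension; each
#' level is shifted to compensate the cascade's group delay, so a symmetric
#' pulse yields a zero-crossing at its apex (within a sample).
#'
#' @param signal a [ppg_signal()] or numeric vector with `fs`.
#' @param levels decomposition depth (default 5, matching a 100 Hz sampling
#'   rate where pulse energy concentrates in levels 4-5).
#' @param fs sampling rate if `signal` is a bare numeric vector.
#' @return object of class `qspline_decomposition`: list with `details` (list
#'   of numeric series), `approximation`, `fs`, `levels`.
#' @export
qspline_decompose <- function(signal, levels = 5L, fs = NULL) {
  signal <- as_signal(signal, fs = fs)
  x <- signal$samples
  n <- length(x)
  if (!is.numeric(levels) || length(levels) != 1L || levels != round(levels) ||
      levels < 1) {
    stop("`levels` must be a single whole number >= 1", call. = FALSE)
  }
  levels <- as.integer(levels)
  fb <- qspline_filters()
  support <- 2^(levels - 1) * max(length(fb$h), length(fb$g))
  if (n <= support) {
    stop(sprintf("signal too short (%d samples) for %d levels (needs > %d)",
                 n, levels, support), call. = FALSE)
  }

  # pad enough for the causal cascade support plus the delay compensation
  pad <- 3L * (2L^levels - 1L) + 2L^levels + 8L
  xe <- x[.sym_index((1L - pad):(n + pad), n)]
  orig <- (pad + 1L):(pad + n)   # positions of the original samples in xe

  details <- vector("list", levels)
  A <- xe
  for (i in seq_len(levels)) {
    step <- 2L^(i - 1L)
    D <- numeric(length(A))
    Anew <- numeric(length(A))
    for (l in seq_along(fb$g)) {
      D <- D + fb$g[l] * .shift_back(A, step * (l - 1L))
    }
    for (l in seq_along(fb$h)) {
      Anew <- Anew + fb$h[l] * .shift_back(A, step * (l - 1L))
    }
    d <- as.integer(round(.qspline_delay(i)))
    details[[i]] <- D[orig + d]
    A <- Anew
  }
  dA <- as.integer(round(1.5 * (2^levels - 1)))
  approximation <- A[orig + dA]

  structure(
    list(details = details, approximation = approximation,
         fs = signal$fs, levels = levels),
    class = "qspline_decomposition"
  )
}

# v delayed by k samples (causal look-back); the left edge is garbage but the
# caller's padding keeps it outside the retained region.
.shift_back <- function(v, k) {
  if (k == 0L) return(v)
  c(v[seq_len(k)], v[seq_len(length(v) - k)])
}

#' @export
print.qspline_decomposition <- function(x, ...) {
  cat(sprintf("<qspline_decomposition> %d levels, %d samples @ %g Hz\n",
              x$levels, length(x$approximation), x$fs))
  invisible(x)
}
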