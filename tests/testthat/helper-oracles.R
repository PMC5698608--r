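# Independent brute-force oracles. Each one recomputes a quantity by direct
# definition (naive loops, enumeration) so the fast implementation can be
# checked against it.

# Band power of a series by raw periodogram, inclusive band [f_lo, f_hi] Hz.
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  sum(sp[f <= fs / 2 & f >= f_lo & f <= f_hi])
}

# interior span (drop `frac`/2 of the samples at each end)
interior <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1L):(n - drop)
}

# A trous quadratic-spline transform by direct per-sample summation over an
# explicitly reflected domain (naive double loops).
oracle_qspline <- function(x, levels) {
  n <- length(x)
  h <- c(0.125, 0.375, 0.375, 0.125)
  g <- c(2, -2)
  refl <- function(i) {
    m <- (i - 1) %% (2 * n)
    ifelse(m < n, m + 1, 2 * n - m)
  }
  P <- 4 * 2^levels + 16
  dom <- (1 - P):(n + P)
  at <- function(vec, t) vec[t - (1 - P) + 1]
  A <- x[refl(dom)]
  W <- vector("list", levels)
  for (i in seq_len(levels)) {
    step <- 2^(i - 1)
    Anew <- rep(NA_real_, length(dom))
    D <- rep(NA_real_, length(dom))
    for (k in seq_along(dom)) {
      t <- dom[k]
      if (t - 3 * step < dom[1]) next
      s_h <- 0
      for (l in 1:4) s_h <- s_h + h[l] * at(A, t - step * (l - 1))
      s_g <- 0
      for (l in 1:2) s_g <- s_g + g[l] * at(A, t - step * (l - 1))
      Anew[k] <- s_h
      D[k] <- s_g
    }
    d <- round(1.5 * (2^(i - 1) - 1) + 0.5 * 2^(i - 1))
    W[[i]] <- vapply(seq_len(n), function(t) at(D, t + d), numeric(1))
    A <- Anew
  }
  W
}

# strict local maxima of |W| above eps by scanning every sample
oracle_modulus_maxima <- function(W, eps) {
  a <- abs(W)
  idx <- integer(0)
  for (i in seq_along(a)) {
    if (i == 1L || i == length(a)) next
    if (a[i] > a[i - 1L] && a[i] > a[i + 1L] && a[i] > eps) idx <- c(idx, i)
  }
  idx
}

# greedy nearest same-sign bipartite matching by repeated global-minimum
# search over the full distance matrix
oracle_cross_level <- function(ma, mb, window) {
  na <- nrow(ma); nb <- nrow(mb)
  if (na == 0L || nb == 0L) return(integer(0))
  D <- outer(ma$index, mb$index, function(x, y) abs(x - y))
  S <- outer(sign(ma$value), sign(mb$value), `==`)
  D[!S | D > window] <- Inf
  kept <- integer(0)
  repeat {
    if (all(!is.finite(D))) break
    k <- which(D == min(D), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]  # tie-break: a then b
    kept <- c(kept, k[1])
    D[k[1], ] <- Inf
    D[, k[2]] <- Inf
  }
  sort(kept)
}

# pair-selection rules applied in explicit stages: (a) drop maxima with no
# opposite-sign companion within the window, (b) pair remaining adjacent
# opposite-sign maxima left to right, (c) resolve refractory conflicts from
# the largest amplitude down
oracle_select_pairs <- function(idx, val, pw, rs) {
  keep <- vapply(seq_along(idx), function(i) {
    any(sign(val) != sign(val[i]) & abs(idx - idx[i]) <= pw)
  }, logical(1))
  idx <- idx[keep]; val <- val[keep]
  zc <- numeric(0); amp <- numeric(0)
  i <- 1L
  while (i < length(idx)) {
    if (sign(val[i]) != sign(val[i + 1L]) && idx[i + 1L] - idx[i] <= pw) {
      zc <- c(zc, floor((idx[i] + idx[i + 1L]) / 2))
      amp <- c(amp, abs(val[i]) + abs(val[i + 1L]))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  alive <- rep(TRUE, length(zc))
  for (k in order(-amp, zc)) {
    if (!alive[k]) next
    clash <- alive & abs(zc - zc[k]) < rs & seq_along(zc) != k
    clash <- clash & amp <= amp[k]   # the larger pair shadows smaller ones
    alive[clash & seq_along(zc) != k] <- FALSE
  }
  data.frame(zero_crossing = zc[alive], amplitude = amp[alive])
}

# exhaustive one-to-one assignment: maximum number of detected/reference
# matches within tolerance, by branch-and-bound enumeration
oracle_match_counts <- function(d, r, tol) {
  best <- 0L
  recurse <- function(j, used, count) {
    if (count + length(r) - j + 1L <= best) return()
    if (j > length(r)) {
      best <<- max(best, count)
      return()
    }
    cand <- which(!used & abs(d - r[j]) <= tol)
    for (cc in cand) {
      used[cc] <- TRUE
      recurse(j + 1L, used, count + 1L)
      used[cc] <- FALSE
    }
    recurse(j + 1L, used, count)
  }
  recurse(1L, logical(length(d)), 0L)
  c(TP = best, FP = length(d) - best, FN = length(r) - best)
}

# quiet generator configs used across tests
clean_config <- function(seed, duration = 30, hr_mean = 72, hr_sd = 0) {
  synthetic_config(
    duration = duration, hr_mean = hr_mean, hr_sd = hr_sd, noise_sd = 0,
    drift = list(freqs = numeric(0), amps = numeric(0), rw_amp = 0),
    artifact_rate = 0, seed = seed
  )
}
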