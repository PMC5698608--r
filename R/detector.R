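# Peak identification from quadratic-spline modulus maxima: adaptive
# per-segment threshold, cross-level persistence (levels 4 and 5), selection
# of opposite-sign maximum pairs, and apex localization at the pair's
# zero-crossing refined on the raw trace.

#' Detector configuration
#'
#' @param seg_len samples per threshold segment (default 256: at least one
#'   heartbeat at 100 Hz).
#' @param threshold_factor fraction of the mean per-segment maximum used as
#'   the modulus-maximum threshold (default 0.5).
#' @param levels_used pair of decomposition levels carrying the pulse energy
#'   at 100 Hz (default `c(4, 5)`).
#' @param refractory_ms minimum physiologically plausible peak spacing
#'   (default 200 ms).
#' @param pairing_window_ms maximum spacing of an opposite-sign maximum pair
#'   (default 300 ms: wider than a systolic upstroke, narrower than one beat
#'   at 200 bpm).
#' @param persistence_window tolerance in samples for a maximum to "exist" on
#'   both levels (default 16, the level-4 support scale).
#' @param refine_window_ms half-width of the apex search around the pair's
#'   zero-crossing (default 100 ms).
#' @param levels total decomposition depth (default 5).
#' @param block_len samples analyzed per iteration (default 1024).
#' @return list of class `detector_config`.
#' @export
detector_config <- function(seg_len = 256L, threshold_factor = 0.5,
                            levels_used = c(4L, 5L), refractory_ms = 200,
                            pairing_window_ms = 300, persistence_window = 16L,
                            refine_window_ms = 100, levels = 5L,
                            block_len = 1024L) {
  cfg <- list(
    seg_len = as.integer(seg_len), threshold_factor = threshold_factor,
    levels_used = as.integer(levels_used), refractory_ms = refractory_ms,
    pairing_window_ms = pairing_window_ms,
    persistence_window = as.integer(persistence_window),
    refine_window_ms = refine_window_ms, levels = as.integer(levels),
    block_len = as.integer(block_len)
  )
  if (cfg$seg_len < 1L) stop("`seg_len` must be >= 1", call. = FALSE)
  if (!is.numeric(threshold_factor) || threshold_factor <= 0 ||
      threshold_factor > 1) {
    stop("`threshold_factor` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$refractory_ms <= 0) stop("`refractory_ms` must be > 0", call. = FALSE)
  if (length(cfg$levels_used) != 2L || any(cfg$levels_used < 1L) ||
      any(cfg$levels_used > cfg$levels)) {
    stop("`levels_used` must be two levels within 1..levels", call. = FALSE)
  }
  structure(cfg, class = "detector_config")
}

#' Adaptive modulus-maximum threshold
#'
#' Splits a coefficient-magnitude series into `N = floor(L / t)` segments of
#' `t` samples (trailing remainder ignored) and returns
#' `factor * mean(per-segment maxima)` — with the default factor, half the
#' average segment maximum.
#'
#' @param magnitudes numeric series of coefficient magnitudes.
#' @param t segment length in samples.
#' @param factor multiplier on the mean segment maximum (default 0.5).
#' @return threshold value.
#' @examples
#' compute_threshold(1:1024, t = 256) # segment maxima 256,512,768,1024 -> 320
#' @export
compute_threshold <- function(magnitudes, t, factor = 0.5) {
  L <- length(magnitudes)
  if (!is.numeric(t) || length(t) != 1L || t != round(t) || t < 1) {
    stop("`t` must be a single whole number >= 1", call. = FALSE)
  }
  if (L < t) stop("series shorter than one segment", call. = FALSE)
  n_seg <- L %/% t
  seg_max <- vapply(seq_len(n_seg), function(j) {
    max(magnitudes[((j - 1L) * t + 1L):(j * t)])
  }, numeric(1))
  factor * mean(seg_max)
}

#' Extract thresholded modulus maxima
#'
#' Strict local maxima of `|W|` exceeding the threshold, carrying the sign of
#' the coefficient.
#'
#' @param W coefficient series.
#' @param level decomposition level (recorded in the output).
#' @param eps threshold (> 0).
#' @return data.frame with columns `index`, `level`, `value`, `magnitude`,
#'   sorted by index; zero rows allowed.
#' @export
extract_modulus_maxima <- function(W, level, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop("`eps` must be a single positive number", call. = FALSE)
  }
  a <- abs(W)
  n <- length(a)
  idx <- integer(0)
  if (n >= 3L) {
    i <- 2L:(n - 1L)
    keep <- a[i] > a[i - 1L] & a[i] > a[i + 1L] & a[i] > eps
    idx <- i[keep]
  }
  data.frame(index = idx, level = rep(as.integer(level), length(idx)),
             value = W[idx], magnitude = a[idx])
}

#' Retain maxima persisting across two levels
#'
#' Keeps each maximum of `maxima_a` that has a same-sign maximum in
#' `maxima_b` within `window` samples; matching is greedy by distance and
#' each `maxima_b` entry is consumed at most once.
#'
#' @param maxima_a,maxima_b data.frames as returned by
#'   [extract_modulus_maxima()], sorted by index.
#' @param window tolerance in samples.
#' @return the retained rows of `maxima_a`, sorted by index.
#' @export
cross_level_retain <- function(maxima_a, maxima_b, window) {
  if (nrow(maxima_a) == 0L || nrow(maxima_b) == 0L) return(maxima_a[0L, ])
  cand <- expand.grid(ia = seq_len(nrow(maxima_a)), ib = seq_len(nrow(maxima_b)))
  cand$dist <- abs(maxima_a$index[cand$ia] - maxima_b$index[cand$ib])
  same_sign <- sign(maxima_a$value[cand$ia]) == sign(maxima_b$value[cand$ib])
  cand <- cand[same_sign & cand$dist <= window, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$ia, cand$ib), , drop = FALSE]
  used_a <- logical(nrow(maxima_a))
  used_b <- logical(nrow(maxima_b))
  for (k in seq_len(nrow(cand))) {
    ia <- cand$ia[k]; ib <- cand$ib[k]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  out <- maxima_a[used_a, , drop = FALSE]
  out[order(out$index), , drop = FALSE]
}

#' Select positive/negative maximum pairs
#'
#' Motion artifacts tend to produce isolated maxima; genuine pulse apexes
#' produce an opposite-sign pair. (a) maxima with no opposite-sign neighbor
#' within the pairing window are dropped; (b) adjacent opposite-sign maxima
#' within the window are paired, with their interposed zero-crossing; (c) of
#' any two pairs whose zero-crossings fall within the refractory period, only
#' the larger-amplitude pair survives.
#'
#' @param maxima data.frame of maxima sorted by index.
#' @param pairing_window_ms,refractory_ms windows in milliseconds.
#' @param fs sampling rate in Hz.
#' @param W optional coefficient series used to place the zero-crossing at
#'   the actual sign change between the two maxima; with `NULL` the midpoint
#'   is used.
#' @return data.frame with columns `pos_index`, `pos_value`, `neg_index`,
#'   `neg_value`, `zero_crossing`, `amplitude`, sorted by `zero_crossing`.
#' @export
select_pairs <- function(maxima, pairing_window_ms, refractory_ms, fs, W = NULL) {
  empty <- data.frame(pos_index = integer(0), pos_value = numeric(0),
                      neg_index = integer(0), neg_value = numeric(0),
                      zero_crossing = integer(0), amplitude = numeric(0))
  m <- nrow(maxima)
  if (m < 2L) return(empty)
  maxima <- maxima[order(maxima$index), , drop = FALSE]
  pw <- ms_to_samples(pairing_window_ms, fs)
  rs <- ms_to_samples(refractory_ms, fs)

  pairs <- empty
  i <- 1L
  while (i < m) {
    gap <- maxima$index[i + 1L] - maxima$index[i]
    if (sign(maxima$value[i]) != sign(maxima$value[i + 1L]) && gap <= pw) {
      a <- maxima[i, ]; b <- maxima[i + 1L, ]
      pos <- if (a$value > 0) a else b
      neg <- if (a$value > 0) b else a
      zc <- .zero_crossing_locus(W, a$index, b$index)
      pairs <- rbind(pairs, data.frame(
        pos_index = pos$index, pos_value = pos$value,
        neg_index = neg$index, neg_value = neg$value,
        zero_crossing = zc, amplitude = abs(pos$value) + abs(neg$value)
      ))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (nrow(pairs) == 0L) return(pairs)

  # refractory rule: greedy by amplitude, larger pair shadows its neighbors
  ord <- order(-pairs$amplitude, pairs$zero_crossing)
  kept_zc <- integer(0)
  keep <- logical(nrow(pairs))
  for (k in ord) {
    if (!any(abs(kept_zc - pairs$zero_crossing[k]) < rs)) {
      keep[k] <- TRUE
      kept_zc <- c(kept_zc, pairs$zero_crossing[k])
    }
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$zero_crossing), , drop = FALSE]
}

# sample index of the sign change of W between i1 and i2 (midpoint fallback)
.zero_crossing_locus <- function(W, i1, i2) {
  lo <- min(i1, i2); hi <- max(i1, i2)
  if (!is.null(W) && hi > lo) {
    for (t in lo:(hi - 1L)) {
      if (W[t] == 0) return(as.integer(t))
      if (sign(W[t]) != sign(W[t + 1L])) {
        return(as.integer(if (abs(W[t]) <= abs(W[t + 1L])) t else t + 1L))
      }
    }
  }
  as.integer(floor((lo + hi) / 2))
}

#' Localize peaks from maximum pairs
#'
#' For each pair, the peak is the argmax of the raw signal within
#' `refine_window_ms` of the pair's zero-crossing. Duplicate localizations
#' collapse to one peak.
#'
#' @param pairs data.frame from [select_pairs()].
#' @param signal the [ppg_signal()] searched for apexes.
#' @param refine_window_ms search half-width in milliseconds (default 100).
#' @return a [peak_set()].
#' @export
locate_peaks <- function(pairs, signal, refine_window_ms = 100) {
  stopifnot(is_ppg_signal(signal))
  n <- length(signal$samples)
  w <- ms_to_samples(refine_window_ms, signal$fs)
  idx <- vapply(seq_len(nrow(pairs)), function(k) {
    zc <- pairs$zero_crossing[k]
    lo <- max(1L, zc - w); hi <- min(n, zc + w)
    win <- signal$samples[lo:hi]
    lo + which.max(win) - 1L
  }, integer(1))
  peak_set(sort(unique(idx)), fs = signal$fs)
}

#' Detect PPG peaks
#'
#' Full modulus-maximum detector: the signal is analyzed in blocks (default
#' 1024 samples; a trailing fragment shorter than one threshold segment is
#' folded into the preceding block). Per block: quadratic-spline
#' decomposition, per-level adaptive thresholds on the magnitudes of the two
#' configured levels, maxima extraction, cross-level retention, pair
#' selection, and apex localization. Peaks closer than the refractory period
#' are resolved in favor of the higher amplitude. Deterministic, and exactly
#' invariant to amplitude scaling and DC offset of the input.
#'
#' @param signal a [ppg_signal()].
#' @param config a [detector_config()].
#' @return a [peak_set()].
#' @export
detect_peaks <- function(signal, config = detector_config()) {
  stopifnot(is_ppg_signal(signal), inherits(config, "detector_config"))
  x <- signal$samples
  n <- length(x)
  if (n < config$seg_len) {
    stop("signal shorter than one threshold segment", call. = FALSE)
  }
  starts <- seq.int(1L, n, by = config$block_len)
  ends <- pmin(starts + config$block_len - 1L, n)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) <
      config$seg_len) {
    ends[length(ends) - 1L] <- n       # fold short tail into previous block
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }

  # each block is analyzed with a margin of neighboring samples so that a
  # maximum pair straddling a block edge is still seen whole; thresholds use
  # the block's own samples and each block emits only its core peaks
  margin <- 256L
  all_idx <- integer(0)
  for (b in seq_along(starts)) {
    lo <- max(1L, starts[b] - margin)
    hi <- min(n, ends[b] + margin)
    blk <- ppg_signal(x[lo:hi], fs = signal$fs, label = signal$label)
    core <- (starts[b] - lo + 1L):(ends[b] - lo + 1L)
    dec <- qspline_decompose(blk, levels = config$levels)
    la <- config$levels_used[1L]; lb <- config$levels_used[2L]
    Wa <- dec$details[[la]]; Wb <- dec$details[[lb]]
    eps_a <- compute_threshold(abs(Wa[core]), config$seg_len, config$threshold_factor)
    eps_b <- compute_threshold(abs(Wb[core]), config$seg_len, config$threshold_factor)
    if (eps_a <= 0 || eps_b <= 0) next   # flat block, nothing to detect
    ma <- extract_modulus_maxima(Wa, la, eps_a)
    mb <- extract_modulus_maxima(Wb, lb, eps_b)
    retained <- cross_level_retain(ma, mb, config$persistence_window)
    pairs <- select_pairs(retained, config$pairing_window_ms,
                          config$refractory_ms, signal$fs, W = Wa)
    if (nrow(pairs) == 0L) next
    pk <- locate_peaks(pairs, blk, config$refine_window_ms)
    glob <- pk$indices + lo - 1L
    all_idx <- c(all_idx, glob[glob >= starts[b] & glob <= ends[b]])
  }
  all_idx <- sort(unique(all_idx))

  # enforce the refractory on the assembled peak list (covers block joints)
  rs <- ms_to_samples(config$refractory_ms, signal$fs)
  if (length(all_idx) > 1L) {
    ord <- order(-x[all_idx], all_idx)
    kept <- integer(0)
    keep <- logical(length(all_idx))
    for (k in ord) {
      if (!any(abs(kept - all_idx[k]) < rs)) {
        keep[k] <- TRUE
        kept <- c(kept, all_idx[k])
      }
    }
    all_idx <- sort(all_idx[keep])
  }
  peak_set(all_idx, fs = signal$fs)
}
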