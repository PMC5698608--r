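# Baseline drift / partial motion artifact suppression by multiresolution
# analysis: the sub-1-Hz wander is captured by the top-level approximation of
# a deep sym8 decomposition and subtracted from the raw trace.

#' Multiresolution decomposition of a signal
#'
#' Decomposes a signal into `level` full-length detail series plus one
#' approximation (smooth) series using an undecimated transform of the chosen
#' orthogonal wavelet. Boundaries are handled by half-point symmetric
#' extension, so edge artifacts are confined to the outer samples. The
#' decomposition is additive: the details and the approximation sum back to
#' the input to machine precision.
#'
#' @param signal a [ppg_signal()] (or numeric vector with `fs` supplied).
#' @param wavelet_id mother wavelet name (default `"sym8"`).
#' @param level decomposition depth; must not exceed
#'   [max_decomposition_level()] for the signal length and filter.
#' @param fs sampling rate, only if `signal` is a bare numeric vector.
#' @return object of class `mra_decomposition`: list with `details` (list of
#'   numeric series, level 1..L), `approximation`, `level`, `wavelet_id`,
#'   `filter_length`, `fs`, `n`.
#' @export
decompose_mra <- function(signal, wavelet_id = "sym8", level = NULL, fs = NULL) {
  signal <- as_signal(signal, fs = fs)
  x <- signal$samples
  n <- length(x)
  filt <- wavelet_filter(wavelet_id)
  lmax <- max_decomposition_level(n, filt$length)  # errors if none valid
  if (is.null(level)) level <- lmax
  if (!is.numeric(level) || length(level) != 1L || level != round(level) || level < 1) {
    stop("`level` must be a single whole number >= 1", call. = FALSE)
  }
  if (level > lmax) {
    stop(sprintf("level %d too deep for %d samples (maximum %d)",
                 as.integer(level), n, lmax), call. = FALSE)
  }
  level <- as.integer(level)

  # half-point symmetric extension to 2n, circular MODWT, truncate back to n
  xe <- c(x, rev(x))
  coeffs <- .modwt(xe, filt, level)
  details <- lapply(seq_len(level), function(j) {
    .modwt_mra_band(coeffs, filt, j)[seq_len(n)]
  })
  approximation <- .modwt_mra_band(coeffs, filt, NULL)[seq_len(n)]

  structure(
    list(
      details = details, approximation = approximation, level = level,
      wavelet_id = wavelet_id, filter_length = filt$length,
      fs = signal$fs, n = n
    ),
    class = "mra_decomposition"
  )
}

#' @export
print.mra_decomposition <- function(x, ...) {
  cat(sprintf("<mra_decomposition> %s, %d levels, %d samples @ %g Hz\n",
              x$wavelet_id, x$level, x$n, x$fs))
  invisible(x)
}

#' Recompose a multiresolution decomposition
#'
#' Sums all detail series and the approximation; by construction this
#' reproduces the decomposed signal.
#'
#' @param decomp an `mra_decomposition`.
#' @return numeric vector of length `decomp$n`.
#' @export
recompose_mra <- function(decomp) {
  stopifnot(inherits(decomp, "mra_decomposition"))
  Reduce(`+`, decomp$details, decomp$approximation)
}

#' Baseline estimate from a multiresolution decomposition
#'
#' The top-level approximation, i.e. the decomposition with every detail band
#' zeroed, captures the sub-1-Hz baseline drift and the low-frequency part of
#' motion artifacts.
#'
#' @param decomp an `mra_decomposition`.
#' @param out_length number of samples to return (defaults to the decomposed
#'   length; cannot exceed it).
#' @return a [ppg_signal()] holding the baseline.
#' @export
estimate_baseline <- function(decomp, out_length = decomp$n) {
  stopifnot(inherits(decomp, "mra_decomposition"))
  if (!is.numeric(out_length) || length(out_length) != 1L ||
      out_length != round(out_length) || out_length < 2 || out_length > decomp$n) {
    stop("`out_length` must be a whole number in [2, n]", call. = FALSE)
  }
  ppg_signal(decomp$approximation[seq_len(out_length)], fs = decomp$fs,
             label = "baseline")
}

#' Subtract an estimated baseline from a signal
#'
#' @param signal,baseline [ppg_signal()]s of equal length and sampling rate.
#' @return corrected [ppg_signal()].
#' @export
correct_signal <- function(signal, baseline) {
  stopifnot(is_ppg_signal(signal), is_ppg_signal(baseline))
  if (length(signal$samples) != length(baseline$samples)) {
    stop("signal and baseline lengths differ", call. = FALSE)
  }
  if (signal$fs != baseline$fs) {
    stop("signal and baseline sampling rates differ", call. = FALSE)
  }
  ppg_signal(signal$samples - baseline$samples, fs = signal$fs,
             label = paste0(signal$label, "_corrected"))
}

#' Baseline-correct a signal, block by block
#'
#' End-to-end suppression stage: the signal is processed in non-overlapping
#' windows (default 1024 samples), each decomposed to its deepest valid level
#' (or a fixed level) and reduced by its own approximation. A final window too
#' short to host even one decomposition level is reduced by its mean.
#'
#' @param signal a [ppg_signal()].
#' @param wavelet_id mother wavelet (default `"sym8"`).
#' @param level `"auto"` (deepest valid level per window) or a fixed integer.
#' @param block_len processing window in samples (default 1024).
#' @return corrected [ppg_signal()].
#' @export
correct_baseline <- function(signal, wavelet_id = "sym8", level = "auto",
                             block_len = 1024L) {
  stopifnot(is_ppg_signal(signal))
  filt <- wavelet_filter(wavelet_id)
  n <- length(signal$samples)
  out <- numeric(n)
  # each block's baseline is estimated from the block plus a margin of real
  # neighboring samples (rather than a mirrored extension at interior joints),
  # so consecutive baseline segments meet without steps; only the core block
  # is corrected from each window
  margin <- 256L
  starts <- seq.int(1L, n, by = block_len)
  for (s in starts) {
    e <- min(s + block_len - 1L, n)
    lo <- max(1L, s - margin)
    hi <- min(n, e + margin)
    win <- signal$samples[lo:hi]
    nw <- length(win)
    core <- (s - lo + 1L):(e - lo + 1L)
    if (nw < 2L * filt$length) {
      out[s:e] <- win[core] - mean(win)   # too short for any level: mean removal
      next
    }
    lev <- if (identical(level, "auto")) NULL else {
      min(as.integer(level), max_decomposition_level(nw, filt$length))
    }
    dec <- decompose_mra(ppg_signal(win, fs = signal$fs), wavelet_id, lev)
    out[s:e] <- win[core] - dec$approximation[core]
  }
  ppg_signal(out, fs = signal$fs, label = paste0(signal$label, "_corrected"))
}
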