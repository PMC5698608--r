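#' Uniformly sampled PPG signal
#'
#' The basic currency between all pipeline stages: a numeric amplitude series
#' with its sampling rate. Amplitudes are in arbitrary units (acquisition
#' hardware typically normalizes to \[0, 1\]).
#'
#' @param samples numeric vector of amplitudes; all finite, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text channel name.
#' @return an object of class `ppg_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' s <- ppg_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 0.01)), fs = 100)
#' s
#' @export
ppg_signal <- function(samples, fs, label = "ppg") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (length(samples) < 2L) {
    stop("a signal needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1L]),
    class = "ppg_signal"
  )
}

#' @export
print.ppg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf(
    "<ppg_signal '%s'> %d samples @ %g Hz (%.2f s), range [%.4g, %.4g]\n",
    x$label, n, x$fs, n / x$fs, min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

is_ppg_signal <- function(x) inherits(x, "ppg_signal")

as_signal <- function(x, fs = NULL, label = "ppg") {
  if (is_ppg_signal(x)) return(x)
  if (is.null(fs)) stop("`fs` is required for a bare numeric signal", call. = FALSE)
  ppg_signal(x, fs = fs, label = label)
}

#' Set of beat (peak) positions
#'
#' Detected or reference peak locations as strictly increasing sample indices
#' (1-based internally; file I/O uses 0-based indices, see [write_peaks()]).
#'
#' @param indices integer vector of sample positions, strictly increasing,
#'   all >= 1. May be empty.
#' @param fs sampling rate of the signal the indices refer to, in Hz.
#' @return an object of class `peak_set` with elements `indices` and `fs`.
#' @export
peak_set <- function(indices, fs) {
  if (length(indices) == 0L) indices <- integer(0)
  if (any(!is.finite(indices)) || any(indices != round(indices))) {
    stop("peak indices must be whole numbers", call. = FALSE)
  }
  indices <- as.integer(round(indices))
  if (any(indices < 1L)) stop("peak indices must be >= 1", call. = FALSE)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(indices = indices, fs = as.numeric(fs)), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  if (length(x$indices) > 0L) {
    show <- utils::head(x$indices, 10L)
    cat(" indices:", paste(show, collapse = " "),
        if (length(x$indices) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$indices)

# milliseconds -> whole samples at rate fs
ms_to_samples <- function(ms, fs) {
  as.integer(round(ms * fs / 1000))
}
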