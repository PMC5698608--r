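# SpO2 from dual-wavelength PPG by the ratio-of-ratios linearization of the
# Lambert-Beer relation: per beat, R = (dI'/I') / (dI/I) across the two
# wavelengths, SpO2 = A * R + B with calibration coefficients A, B.

#' Per-beat pulse features
#'
#' For every peak after the first: the peak amplitude `I_max`, the preceding
#' trough (minimum between the previous and the current peak), and their
#' difference `dI_max`.
#'
#' @param signal a [ppg_signal()].
#' @param peaks a [peak_set()] on that signal with at least two peaks.
#' @return data.frame with columns `peak_index`, `peak_value`, `trough_value`,
#'   `delta`; attribute `fs` carries the sampling rate.
#' @export
pulse_features <- function(signal, peaks) {
  stopifnot(is_ppg_signal(signal), inherits(peaks, "peak_set"))
  p <- peaks$indices
  if (length(p) < 2L) stop("need at least 2 peaks", call. = FALSE)
  if (max(p) > length(signal$samples)) {
    stop("peak index beyond signal end", call. = FALSE)
  }
  k <- 2L:length(p)
  trough <- vapply(k, function(i) min(signal$samples[p[i - 1L]:p[i]]), numeric(1))
  out <- data.frame(
    peak_index = p[k],
    peak_value = signal$samples[p[k]],
    trough_value = trough,
    delta = signal$samples[p[k]] - trough
  )
  attr(out, "fs") <- signal$fs
  out
}

#' SpO2 from matched dual-wavelength beat features
#'
#' Beats from the two channels are matched one-to-one by peak-index
#' proximity. Per beat the normalized pulsatile ratio `dI/I_max` is formed in
#' each channel; their quotient `R = (dI'/I') / (dI/I)` (second wavelength
#' over first) enters either the linear calibration `SpO2 = A * R + B`
#' (default) or the exact logarithmic form
#' `A * log10(1 - dI'/I') / log10(1 - dI/I) + B`. Beats with zero pulsatility
#' in the first channel, or (log form) a ratio outside `[0, 1)`, are skipped
#' with a warning.
#'
#' @param features_red features of the first (unprimed, e.g. 660 nm)
#'   channel, from [pulse_features()].
#' @param features_ir features of the second (primed, e.g. 940 nm) channel.
#' @param params list with calibration coefficients `A` and `B`.
#' @param form `"linear"` (default) or `"log"`.
#' @param tolerance_ms beat matching tolerance (default 150 ms).
#' @return list of class `spo2_result`: `per_beat` (SpO2 per matched beat),
#'   `R` (per-beat ratio of ratios), `median` and `n_beats`.
#' @export
compute_spo2 <- function(features_red, features_ir, params,
                         form = c("linear", "log"), tolerance_ms = 150) {
  form <- match.arg(form)
  if (!is.list(params) || !all(c("A", "B") %in% names(params)) ||
      !is.finite(params$A) || !is.finite(params$B)) {
    stop("`params` must supply finite calibration coefficients A and B",
         call. = FALSE)
  }
  fs <- attr(features_red, "fs")
  fs2 <- attr(features_ir, "fs")
  if (is.null(fs) || is.null(fs2) || fs != fs2) {
    stop("feature tables must carry the same sampling rate", call. = FALSE)
  }
  m <- .match_beats(features_red$peak_index, features_ir$peak_index,
                    ms_to_samples(tolerance_ms, fs))
  if (nrow(m) == 0L) stop("no beats could be matched across channels", call. = FALSE)

  ratio_red <- features_red$delta[m$i] / features_red$peak_value[m$i]
  ratio_ir <- features_ir$delta[m$j] / features_ir$peak_value[m$j]
  ok <- is.finite(ratio_red) & is.finite(ratio_ir) & ratio_red != 0
  if (form == "log") {
    ok <- ok & ratio_red > 0 & ratio_red < 1 & ratio_ir >= 0 & ratio_ir < 1 &
      log10(1 - ratio_red) != 0
  }
  if (any(!ok)) {
    warning(sprintf("%d beat(s) skipped (zero pulsatility or ratio outside the valid domain)",
                    sum(!ok)), call. = FALSE)
  }
  if (!any(ok)) stop("all beats were skipped; no SpO2 computable", call. = FALSE)

  R <- ratio_ir[ok] / ratio_red[ok]
  spo2 <- if (form == "linear") {
    params$A * R + params$B
  } else {
    params$A * log10(1 - ratio_ir[ok]) / log10(1 - ratio_red[ok]) + params$B
  }
  structure(
    list(per_beat = spo2, R = R, median = stats::median(spo2),
         n_beats = length(spo2)),
    class = "spo2_result"
  )
}

# order-preserving one-to-one matching of two sorted index vectors (same DP
# as peak matching, returning the matched index pairs)
.match_beats <- function(a, b, tol) {
  na <- length(a); nb <- length(b)
  f <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(f[i, j + 1L], f[i + 1L, j])
      if (abs(a[i] - b[j]) <= tol) best <- max(best, f[i, j] + 1L)
      f[i + 1L, j + 1L] <- best
    }
  }
  i <- na; j <- nb
  mi <- integer(0); mj <- integer(0)
  while (i > 0L && j > 0L) {
    if (abs(a[i] - b[j]) <= tol && f[i + 1L, j + 1L] == f[i, j] + 1L) {
      mi <- c(i, mi); mj <- c(j, mj)
      i <- i - 1L; j <- j - 1L
    } else if (f[i, j + 1L] >= f[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  data.frame(i = mi, j = mj)
}

#' @export
print.spo2_result <- function(x, ...) {
  cat(sprintf("<spo2_result> %d beats, median SpO2 = %.2f (median R = %.4f)\n",
              x$n_beats, x$median, stats::median(x$R)))
  invisible(x)
}
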