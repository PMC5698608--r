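# Detector evaluation: one-to-one matching of detected against reference
# beats within a tolerance, and the FP/FN error percentage.

# half-up rounding (R's round() is round-half-even); table formatting rule
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Match detected peaks against reference annotations
#'
#' Optimal one-to-one matching within `tolerance_ms`. Both sets are sorted,
#' so the maximum matching can be realized order-preservingly; it is computed
#' by dynamic programming. Unmatched detected peaks are false positives,
#' unmatched reference peaks false negatives.
#'
#' @param detected,reference [peak_set()]s at the same sampling rate.
#' @param tolerance_ms matching tolerance (default 150 ms, below half a beat
#'   at 200 bpm).
#' @return named integer vector `c(TP, FP, FN)` with
#'   `TP + FN == length(reference)` and `TP + FP == length(detected)`.
#' @export
match_peaks <- function(detected, reference, tolerance_ms = 150) {
  stopifnot(inherits(detected, "peak_set"), inherits(reference, "peak_set"))
  if (detected$fs != reference$fs) {
    stop("detected and reference sampling rates differ", call. = FALSE)
  }
  tol <- ms_to_samples(tolerance_ms, detected$fs)
  d <- detected$indices
  r <- reference$indices
  nd <- length(d); nr <- length(r)
  if (nd == 0L || nr == 0L) {
    return(c(TP = 0L, FP = nd, FN = nr))
  }
  # f[i+1, j+1] = max matches using d[1..i], r[1..j]
  f <- matrix(0L, nd + 1L, nr + 1L)
  for (i in seq_len(nd)) {
    for (j in seq_len(nr)) {
      best <- max(f[i, j + 1L], f[i + 1L, j])
      if (abs(d[i] - r[j]) <= tol) best <- max(best, f[i, j] + 1L)
      f[i + 1L, j + 1L] <- best
    }
  }
  tp <- f[nd + 1L, nr + 1L]
  c(TP = tp, FP = nd - tp, FN = nr - tp)
}

#' Beat detection error percentage
#'
#' `100 * (FP + FN) / RB`, where RB is the number of real beats, FP the false
#' detections and FN the missed beats; reported to two decimals (half-up).
#'
#' @param RB real beat count (>= 1).
#' @param FP,FN false positive and false negative counts (>= 0).
#' @return error percentage, rounded to two decimals.
#' @examples
#' detection_error(70, 1, 2) # 4.29
#' detection_error(70, 1, 0) # 1.43
#' @export
detection_error <- function(RB, FP, FN) {
  if (!is.numeric(RB) || length(RB) != 1L || RB != round(RB) || RB < 1) {
    stop("`RB` must be a single whole number >= 1", call. = FALSE)
  }
  if (FP < 0 || FN < 0) stop("`FP` and `FN` must be >= 0", call. = FALSE)
  round_half_up(100 * (FP + FN) / RB, 2L)
}

#' Evaluate a detector run against reference beats
#'
#' @inheritParams match_peaks
#' @return list of class `evaluation_result` with `RB`, `TP`, `FP`, `FN` and
#'   `error_percent`.
#' @export
evaluate_detection <- function(detected, reference, tolerance_ms = 150) {
  counts <- match_peaks(detected, reference, tolerance_ms)
  RB <- length(reference$indices)
  if (RB < 1L) stop("reference annotation is empty", call. = FALSE)
  structure(
    list(RB = RB, TP = counts[["TP"]], FP = counts[["FP"]],
         FN = counts[["FN"]],
         error_percent = detection_error(RB, counts[["FP"]], counts[["FN"]])),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> RB=%d TP=%d FP=%d FN=%d error=%.2f%%\n",
              x$RB, x$TP, x$FP, x$FN, x$error_percent))
  invisible(x)
}
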