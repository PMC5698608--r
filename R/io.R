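# File formats, run configuration and the umbrella pipeline. Signals travel
# as CSV (either `time_s,amplitude` or a single `amplitude` column plus an
# explicit sampling rate); peak sets as one 0-based sample index per line.

#' Read a signal from CSV
#'
#' Accepts a two-column `time_s,amplitude` file (sampling rate inferred from
#' the time stamps, which must be uniform to within 1% jitter) or a
#' single-column `amplitude` file with `fs` supplied.
#'
#' @param path CSV file path.
#' @param fs sampling rate override (required for single-column files).
#' @param label channel name for the resulting signal.
#' @return a [ppg_signal()].
#' @export
read_signal <- function(path, fs = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (all(c("time_s", "amplitude") %in% names(df))) {
    tm <- suppressWarnings(as.numeric(df$time_s))
    amp <- suppressWarnings(as.numeric(df$amplitude))
    bad <- which(!is.finite(tm) | !is.finite(amp))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric or missing value at data line %d",
                   path, bad[1L]), call. = FALSE)
    }
    dt <- diff(tm)
    med <- stats::median(dt)
    if (med <= 0 || any(abs(dt - med) > 0.01 * med)) {
      stop(sprintf("%s: time stamps are not uniform (jitter > 1%% of the sampling interval)",
                   path), call. = FALSE)
    }
    fs_file <- 1 / med
    if (is.null(fs)) fs <- fs_file
  } else if ("amplitude" %in% names(df)) {
    if (is.null(fs)) {
      stop(sprintf("%s: single-column file needs an explicit sampling rate (`fs`)",
                   path), call. = FALSE)
    }
    amp <- suppressWarnings(as.numeric(df$amplitude))
    bad <- which(!is.finite(amp))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric or missing value at data line %d",
                   path, bad[1L]), call. = FALSE)
    }
  } else {
    stop(sprintf("%s: expected columns `time_s,amplitude` or `amplitude`", path),
         call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  ppg_signal(amp, fs = fs, label = label)
}

#' Write a signal to CSV
#'
#' Writes `time_s,amplitude` with 17 significant digits so that a read-back
#' reproduces the doubles bit-exactly. Locale-independent ('.' decimal
#' separator).
#'
#' @param signal a [ppg_signal()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(is_ppg_signal(signal))
  tm <- (seq_along(signal$samples) - 1) / signal$fs
  lines <- c("time_s,amplitude",
             sprintf("%.17g,%.17g", tm, signal$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write peak annotation files
#'
#' One 0-based sample index per line; blank files are valid (empty peak
#' set). Indices must be non-negative and strictly increasing.
#'
#' @param path annotation file.
#' @param fs sampling rate the indices refer to.
#' @return a [peak_set()] (indices converted to 1-based internally).
#' @export
read_peaks <- function(path, fs) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L) return(peak_set(integer(0), fs))
  v <- suppressWarnings(as.numeric(ln))
  bad <- which(!is.finite(v) | v != round(v))
  if (length(bad) > 0L) {
    stop(sprintf("%s: not a whole number at line %d", path, bad[1L]), call. = FALSE)
  }
  if (any(v < 0)) stop(sprintf("%s: negative peak index", path), call. = FALSE)
  if (length(v) > 1L && any(diff(v) <= 0)) {
    stop(sprintf("%s: peak indices must be strictly increasing", path), call. = FALSE)
  }
  peak_set(v + 1L, fs)
}

#' @rdname read_peaks
#' @param peaks a [peak_set()].
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  writeLines(as.character(peaks$indices - 1L), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' All tunables of the suppression, detection, evaluation and SpO2 stages in
#' one (JSON-serializable) object. Unknown keys are rejected.
#'
#' @param ... overrides as nested lists, e.g.
#'   `run_config(detector = list(refractory_ms = 250))`.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    suppression = list(enabled = TRUE, wavelet = "sym8", level = "auto",
                       block_len = 1024L),
    detector = list(levels = 5L, seg_len = 256L, threshold_factor = 0.5,
                    levels_used = c(4L, 5L), refractory_ms = 200,
                    pairing_window_ms = 300, persistence_window = 16L,
                    refine_window_ms = 100, block_len = 1024L),
    evaluation = list(tolerance_ms = 150),
    spo2 = list(A = NULL, B = NULL, form = "linear"),
    verbosity = 1L
  )
  overrides <- list(...)
  cfg <- .merge_config(defaults, overrides, path = "")
  structure(cfg, class = "run_config")
}

.merge_config <- function(base, overrides, path) {
  for (nm in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        stop(sprintf("configuration key %s must be a list", full), call. = FALSE)
      }
      base[[nm]] <- .merge_config(base[[nm]], overrides[[nm]], full)
    } else {
      base[nm] <- overrides[nm]   # keeps NULL-able leaves (spo2 A/B)
    }
  }
  base
}

#' @rdname run_config
#' @param path JSON file to read or write.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

.detector_from_run_config <- function(config) {
  d <- config$detector
  detector_config(
    seg_len = d$seg_len, threshold_factor = d$threshold_factor,
    levels_used = d$levels_used, refractory_ms = d$refractory_ms,
    pairing_window_ms = d$pairing_window_ms,
    persistence_window = d$persistence_window,
    refine_window_ms = d$refine_window_ms, levels = d$levels,
    block_len = d$block_len
  )
}

#' Run the full correction + detection pipeline
#'
#' Baseline-corrects the signal (unless disabled), detects peaks, and — when
#' a reference annotation is supplied — evaluates them. Deterministic: the
#' same signal and configuration always give the same report.
#'
#' @param signal a [ppg_signal()] or a CSV path readable by [read_signal()].
#' @param config a [run_config()].
#' @param reference optional [peak_set()] or annotation file path.
#' @param no_correct skip the suppression stage (detect on the raw trace).
#' @param out_dir optional directory; when given, writes `corrected.csv`,
#'   `peaks.txt` and `report.json` there.
#' @param fs sampling rate, needed when `signal` is a single-column CSV.
#' @return list of class `pipeline_report`: `peaks`, `corrected`,
#'   `evaluation` (or `NULL`), `config`, `config_hash`, `n_samples`, `fs`.
#' @export
run_pipeline <- function(signal, config = run_config(), reference = NULL,
                         no_correct = FALSE, out_dir = NULL, fs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(signal)) signal <- read_signal(signal, fs = fs)
  stopifnot(is_ppg_signal(signal))
  if (is.character(reference)) reference <- read_peaks(reference, signal$fs)

  log_msg <- function(fmt, ...) {
    if (isTRUE(config$verbosity >= 1L)) message(sprintf(fmt, ...))
  }
  log_msg("pipeline: %d samples @ %g Hz, config %s", length(signal$samples),
          signal$fs, config_hash(config))

  corrected <- if (!no_correct && isTRUE(config$suppression$enabled)) {
    log_msg("suppression: %s, level=%s, block=%d", config$suppression$wavelet,
            as.character(config$suppression$level), config$suppression$block_len)
    correct_baseline(signal, wavelet_id = config$suppression$wavelet,
                     level = config$suppression$level,
                     block_len = config$suppression$block_len)
  } else {
    log_msg("suppression: skipped")
    signal
  }

  peaks <- detect_peaks(corrected, .detector_from_run_config(config))
  log_msg("detector: %d peaks", length(peaks$indices))

  evaluation <- NULL
  if (!is.null(reference)) {
    evaluation <- evaluate_detection(peaks, reference,
                                     config$evaluation$tolerance_ms)
    log_msg("evaluation: RB=%d FP=%d FN=%d error=%.2f%%", evaluation$RB,
            evaluation$FP, evaluation$FN, evaluation$error_percent)
  }

  report <- structure(
    list(peaks = peaks, corrected = corrected, evaluation = evaluation,
         config = config, config_hash = config_hash(config),
         n_samples = length(signal$samples), fs = signal$fs),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signal(corrected, file.path(out_dir, "corrected.csv"))
    write_peaks(peaks, file.path(out_dir, "peaks.txt"))
    json <- list(
      config_hash = report$config_hash, n_samples = report$n_samples,
      fs = report$fs, n_peaks = length(peaks$indices),
      peaks_0based = peaks$indices - 1L
    )
    if (!is.null(evaluation)) {
      json$evaluation <- list(RB = evaluation$RB, TP = evaluation$TP,
                              FP = evaluation$FP, FN = evaluation$FN,
                              error_percent = evaluation$error_percent)
    }
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples @ %g Hz, %d peaks\n",
              x$n_samples, x$fs, length(x$peaks$indices)))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
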