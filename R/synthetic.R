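# Seeded synthetic PPG generator. Emulates the features that matter to the
# pipeline: quasi-periodic pulse waves with energy in 1-10 Hz, additive
# nonstationary sub-1-Hz drift, sparse low-frequency artifact bumps, white
# noise, beat-interval variability — with ground-truth systolic apexes and
# every additive component returned separately.

#' Synthetic PPG configuration
#'
#' Regime presets emulate three acquisition postures: `sitting` (faint
#' respiratory drift, no artifacts), `raising_hand` (drift comparable to the
#' pulse amplitude at 0.1-0.3 Hz), `walking` (drift at twice the pulse
#' amplitude plus ~4 artifact events per minute). Explicit arguments override
#' the preset.
#'
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz (default 100).
#' @param hr_mean,hr_sd mean and beat-to-beat SD of heart rate in bpm;
#'   `hr_sd` must stay below `hr_mean / 2`.
#' @param template pulse shape: two Gaussian bumps — systolic (SD
#'   `sys_sigma` s, unit height times `amplitude`) and dicrotic
#'   (`dicrotic_delay` s later, `dicrotic_frac` relative height,
#'   SD `dicrotic_sigma` s).
#' @param drift list with `freqs` and `amps` of sub-1-Hz sinusoids (random
#'   phases) and `rw_amp`, the peak amplitude of a centered random walk.
#' @param artifact_rate artifact events per minute (Poisson).
#' @param artifact_duration,artifact_amp ranges (s; amplitude units) an
#'   event's Gaussian bump is drawn from; amplitude sign is random.
#' @param noise_sd white noise SD in amplitude units.
#' @param seed integer seed; a fixed seed makes the output bit-reproducible.
#' @param regime `NULL` or one of `"sitting"`, `"raising_hand"`, `"walking"`.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration = 30, fs = 100, hr_mean = 75, hr_sd = 3,
                             template = list(sys_sigma = 0.06,
                                             dicrotic_delay = 0.30,
                                             dicrotic_frac = 0.35,
                                             dicrotic_sigma = 0.10,
                                             amplitude = 1),
                             drift = NULL, artifact_rate = NULL,
                             artifact_duration = c(0.5, 1.5),
                             artifact_amp = NULL, noise_sd = NULL,
                             seed = 1L, regime = NULL) {
  preset <- list(
    drift = list(freqs = 0.25, amps = 0.05, rw_amp = 0),
    artifact_rate = 0, artifact_amp = c(0.5, 1.5), noise_sd = 0.01
  )
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("sitting", "raising_hand", "walking"))
    preset <- switch(regime,
      sitting = list(drift = list(freqs = 0.25, amps = 0.05, rw_amp = 0),
                     artifact_rate = 0, artifact_amp = c(0.5, 1.5),
                     noise_sd = 0.01),
      raising_hand = list(drift = list(freqs = c(0.12, 0.28),
                                       amps = c(0.6, 0.4), rw_amp = 0.2),
                          artifact_rate = 0, artifact_amp = c(0.5, 1.5),
                          noise_sd = 0.01),
      walking = list(drift = list(freqs = c(0.15, 0.35),
                                  amps = c(1.2, 0.8), rw_amp = 0.5),
                     artifact_rate = 4, artifact_amp = c(0.5, 1.5),
                     noise_sd = 0.02)
    )
  }
  cfg <- list(
    duration = duration, fs = fs, hr_mean = hr_mean, hr_sd = hr_sd,
    template = template,
    drift = if (is.null(drift)) preset$drift else drift,
    artifact_rate = if (is.null(artifact_rate)) preset$artifact_rate else artifact_rate,
    artifact_duration = artifact_duration,
    artifact_amp = if (is.null(artifact_amp)) preset$artifact_amp else artifact_amp,
    noise_sd = if (is.null(noise_sd)) preset$noise_sd else noise_sd,
    seed = as.integer(seed), regime = regime
  )
  if (cfg$fs <= 0 || cfg$duration <= 0) {
    stop("`fs` and `duration` must be positive", call. = FALSE)
  }
  if (cfg$hr_mean <= 0) stop("`hr_mean` must be positive", call. = FALSE)
  if (cfg$hr_sd < 0 || cfg$hr_sd >= cfg$hr_mean / 2) {
    stop("degenerate config: need 0 <= hr_sd < hr_mean / 2", call. = FALSE)
  }
  if (length(cfg$drift$freqs) > 0 && any(cfg$drift$freqs >= 1)) {
    stop("drift sinusoid frequencies must be below 1 Hz", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# run expr with a private, seeded RNG stream; caller's RNG state untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic PPG record with ground truth
#'
#' Beat times are drawn from the configured heart-rate statistics (intervals
#' truncated to stay positive), each beat stamps the pulse template, and
#' drift, artifacts and white noise are added. All additive components are
#' returned separately, so `raw = clean + drift + artifacts + noise` holds
#' exactly; ground-truth peaks are the systolic apexes of the clean
#' component.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_ppg` with `signal` (raw), `peaks`
#'   (ground truth [peak_set()]), `clean`, `drift`, `artifacts`, `noise`
#'   ([ppg_signal()]s / numeric components) and `config`.
#' @export
generate_ppg <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    fs <- config$fs
    n <- as.integer(round(config$duration * fs))
    tt <- (seq_len(n) - 1) / fs

    mean_rr <- 60 / config$hr_mean
    sd_rr <- 60 * config$hr_sd / config$hr_mean^2
    beats <- numeric(0)
    t_beat <- mean_rr / 2               # first apex half an interval in
    while (t_beat < config$duration) {
      beats <- c(beats, t_beat)
      rr <- stats::rnorm(1, mean_rr, sd_rr)
      rr <- max(rr, 0.3 * mean_rr)      # truncate to positive intervals
      t_beat <- t_beat + rr
    }

    tpl <- config$template
    clean <- numeric(n)
    for (b in beats) {
      clean <- clean + tpl$amplitude * (
        exp(-(tt - b)^2 / (2 * tpl$sys_sigma^2)) +
          tpl$dicrotic_frac *
            exp(-(tt - b - tpl$dicrotic_delay)^2 / (2 * tpl$dicrotic_sigma^2))
      )
    }
    # ground truth: actual apex of the clean trace near each stamped beat
    peaks <- vapply(beats, function(b) {
      c0 <- as.integer(round(b * fs)) + 1L
      lo <- max(1L, c0 - 5L); hi <- min(n, c0 + 5L)
      lo + which.max(clean[lo:hi]) - 1L
    }, integer(1))
    peaks <- sort(unique(peaks))

    drift <- numeric(n)
    dr <- config$drift
    for (k in seq_along(dr$freqs)) {
      drift <- drift + dr$amps[k] * sin(2 * pi * dr$freqs[k] * tt +
                                          stats::runif(1, 0, 2 * pi))
    }
    if (isTRUE(dr$rw_amp > 0)) {
      rw <- cumsum(stats::rnorm(n))
      rw <- rw - mean(rw)
      mx <- max(abs(rw))
      if (mx > 0) drift <- drift + dr$rw_amp * rw / mx
    }

    artifacts <- numeric(n)
    if (config$artifact_rate > 0) {
      n_ev <- stats::rpois(1, config$artifact_rate * config$duration / 60)
      for (e in seq_len(n_ev)) {
        centre <- stats::runif(1, 0, config$duration)
        dur <- stats::runif(1, config$artifact_duration[1], config$artifact_duration[2])
        amp <- stats::runif(1, config$artifact_amp[1], config$artifact_amp[2]) *
          sample(c(-1, 1), 1)
        artifacts <- artifacts + amp * exp(-(tt - centre)^2 / (2 * (dur / 4)^2))
      }
    }

    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)

    raw <- clean + drift + artifacts + noise
    structure(
      list(
        signal = ppg_signal(raw, fs, label = "synthetic"),
        peaks = peak_set(peaks, fs),
        clean = ppg_signal(clean, fs, label = "clean"),
        drift = ppg_signal(drift, fs, label = "drift"),
        artifacts = artifacts, noise = noise, config = config
      ),
      class = "synthetic_ppg"
    )
  })
}

#' @export
print.synthetic_ppg <- function(x, ...) {
  cat(sprintf("<synthetic_ppg> %g s @ %g Hz, %d true beats, regime=%s, seed=%d\n",
              x$config$duration, x$config$fs, length(x$peaks$indices),
              if (is.null(x$config$regime)) "custom" else x$config$regime,
              x$config$seed))
  invisible(x)
}

#' Generate a dual-wavelength synthetic record
#'
#' Two channels sharing the same beat train, with DC levels and pulsatile
#' amplitudes arranged so the per-beat ratio of ratios equals `ratio` (the
#' AC fractions are solved exactly for the nominal unit-height apex). Drift
#' and noise from `config` corrupt each channel, scaled to its AC amplitude.
#'
#' @param config a [synthetic_config()].
#' @param ratio target ratio of ratios `(dI'/I') / (dI/I)` (> 0), second
#'   (ir) over first (red) channel.
#' @param dc_red,dc_ir DC levels of the two channels (> 0).
#' @param base_pulsatility nominal `dI/I` of the red channel (default 0.04).
#' @return list of class `synthetic_dual` with `red`, `ir` ([ppg_signal()]s),
#'   `peaks` (shared ground truth) and `config`.
#' @export
generate_dual_channel <- function(config = synthetic_config(), ratio = 0.8,
                                  dc_red = 2, dc_ir = 2,
                                  base_pulsatility = 0.04) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(ratio) || ratio <= 0) stop("`ratio` must be > 0", call. = FALSE)
  if (dc_red <= 0 || dc_ir <= 0) stop("DC levels must be > 0", call. = FALSE)
  rho_red <- base_pulsatility
  rho_ir <- ratio * rho_red
  if (rho_ir >= 1 || rho_red >= 1) {
    stop("`ratio` too large for the chosen base pulsatility", call. = FALSE)
  }
  rec <- generate_ppg(config)
  amp <- max(rec$clean$samples)
  clean_norm <- rec$clean$samples / amp          # apex 1, trough ~0
  corrupt <- (rec$drift$samples + rec$artifacts) / max(amp, 1e-12)
  a_red <- rho_red * dc_red / (1 - rho_red)      # solves a/(dc+a) = rho
  a_ir <- rho_ir * dc_ir / (1 - rho_ir)
  .with_seed(config$seed + 1L, {
    n1 <- if (config$noise_sd > 0) stats::rnorm(length(clean_norm), 0, config$noise_sd) else 0
    n2 <- if (config$noise_sd > 0) stats::rnorm(length(clean_norm), 0, config$noise_sd) else 0
    red <- dc_red + a_red * (clean_norm + corrupt + n1)
    ir <- dc_ir + a_ir * (clean_norm + corrupt + n2)
    structure(
      list(red = ppg_signal(red, config$fs, "red"),
           ir = ppg_signal(ir, config$fs, "ir"),
           peaks = rec$peaks, config = config, ratio = ratio),
      class = "synthetic_dual"
    )
  })
}
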