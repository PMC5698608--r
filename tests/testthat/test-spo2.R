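mk_features <- function(peak_value, delta, index = NULL, fs = 100) {
  n <- length(peak_value)
  if (is.null(index)) index <- seq(100, by = 100, length.out = n)
  out <- data.frame(peak_index = as.integer(index), peak_value = peak_value,
                    trough_value = peak_value - delta, delta = delta)
  attr(out, "fs") <- fs
  out
}

test_that("pulse features measure peak-to-trough excursions", {
  tt <- (0:999) / 100
  sine <- ppg_signal(0.4 * sin(2 * pi * 1 * tt), fs = 100)
  peaks <- peak_set(which(diff(sign(diff(sine$samples))) == -2) + 1L, 100)
  pf <- pulse_features(sine, peaks)
  expect_equal(pf$delta, rep(0.8, nrow(pf)), tolerance = 1e-3)

  const <- ppg_signal(rep(2, 500), fs = 100)
  pfc <- pulse_features(const, peak_set(c(100, 200, 300), 100))
  expect_equal(pfc$delta, c(0, 0))

  expect_error(pulse_features(sine, peak_set(100, 100)), "at least 2 peaks")

  # synthetic train: excursion within 2% of the template peak-to-foot height
  rec <- generate_ppg(clean_config(seed = 2, duration = 20, hr_mean = 70))
  pf2 <- pulse_features(rec$clean, rec$peaks)
  expect_true(all(abs(pf2$delta - 1) < 0.02))
})

test_that("ratio-of-ratios arithmetic follows the linear calibration", {
  # dI'/I' = 0.01 over dI/I = 0.02 -> R = 0.5; A=25, B=60 -> 72.5
  red <- mk_features(peak_value = c(1, 1, 1), delta = c(0.02, 0.02, 0.02))
  ir <- mk_features(peak_value = c(1, 1, 1), delta = c(0.01, 0.01, 0.01))
  res <- compute_spo2(red, ir, list(A = 25, B = 60))
  expect_equal(res$per_beat, rep(72.5, 3))
  expect_equal(res$median, 72.5)

  # identical channels: R = 1 -> A + B
  res1 <- compute_spo2(red, red, list(A = 25, B = 60))
  expect_equal(res1$median, 85)

  # SpO2 is affine in R with slope exactly A
  resA <- compute_spo2(red, ir, list(A = 40, B = 60))
  expect_equal(resA$median - 60, 40 * 0.5)
})

test_that("per-channel amplitude scaling leaves R unchanged", {
  red <- mk_features(peak_value = c(2, 2.2), delta = c(0.05, 0.06))
  ir <- mk_features(peak_value = c(3, 2.9), delta = c(0.04, 0.05))
  r0 <- compute_spo2(red, ir, list(A = 1, B = 0))$R
  red_scaled <- mk_features(peak_value = 7 * c(2, 2.2), delta = 7 * c(0.05, 0.06))
  ir_scaled <- mk_features(peak_value = 0.3 * c(3, 2.9), delta = 0.3 * c(0.04, 0.05))
  expect_equal(compute_spo2(red_scaled, ir_scaled, list(A = 1, B = 0))$R, r0)
})

test_that("log form agrees with the linear form at small pulsatility", {
  red <- mk_features(peak_value = c(1, 1), delta = c(0.002, 0.002))
  ir <- mk_features(peak_value = c(1, 1), delta = c(0.001, 0.001))
  lin <- compute_spo2(red, ir, list(A = 25, B = 60), form = "linear")
  lg <- compute_spo2(red, ir, list(A = 25, B = 60), form = "log")
  expect_equal(lg$median, lin$median, tolerance = 1e-2)
})

test_that("degenerate beats are skipped, never clamped", {
  red <- mk_features(peak_value = c(1, 1), delta = c(0, 0.02))
  ir <- mk_features(peak_value = c(1, 1), delta = c(0.01, 0.01))
  expect_warning(res <- compute_spo2(red, ir, list(A = 1, B = 0)), "skipped")
  expect_identical(res$n_beats, 1L)
  # ratio >= 1 is outside the log-form domain
  red2 <- mk_features(peak_value = c(1, 1), delta = c(1.0, 0.02))
  expect_warning(res2 <- compute_spo2(red2, ir, list(A = 1, B = 0), form = "log"),
                 "skipped")
  expect_identical(res2$n_beats, 1L)
  red3 <- mk_features(peak_value = c(1, 1), delta = c(0, 0))
  expect_warning(expect_error(compute_spo2(red3, ir, list(A = 1, B = 0)),
                              "all beats"), "skipped")
})

test_that("configured ratio is recovered from dual-channel records", {
  for (r0 in c(0.5, 0.8)) {
    dual <- generate_dual_channel(clean_config(seed = 3, duration = 30),
                                  ratio = r0)
    red_f <- pulse_features(dual$red, dual$peaks)
    ir_f <- pulse_features(dual$ir, dual$peaks)
    res <- compute_spo2(red_f, ir_f, list(A = 1, B = 0))
    expect_lt(abs(res$median - r0), 0.02)
  }
})
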