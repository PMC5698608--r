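test_that("maximum decomposition level follows the truncated log2 rule", {
  expect_identical(max_decomposition_level(1024, 16), 6L)
  expect_identical(max_decomposition_level(4096, 16), 8L)  # fix(log2(4096/15)) = fix(8.09)
  expect_identical(max_decomposition_level(512, 16), 5L)
  # 16 samples with a 16-tap filter cannot host a level
  expect_error(max_decomposition_level(16, 16), "no valid decomposition level")
  expect_error(max_decomposition_level(-4, 16), "whole number")
  expect_error(max_decomposition_level(1024, 1), "whole number")
})

test_that("decomposition annihilates constants and reconstructs perfectly", {
  const <- ppg_signal(rep(0.73, 1024), fs = 100)
  dec <- decompose_mra(const, level = 6)
  detail_energy <- sum(vapply(dec$details, function(d) sum(d^2), numeric(1)))
  expect_lt(detail_energy, 1e-10 * 0.73^2)
  expect_equal(dec$approximation, rep(0.73, 1024), tolerance = 1e-8)

  set.seed(101)
  for (n in c(300, 1024)) {
    x <- cumsum(rnorm(n)) / 10 + sin(2 * pi * 1.3 * (0:(n - 1)) / 100)
    dec <- decompose_mra(ppg_signal(x, 100))
    rec <- recompose_mra(dec)
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
    expect_length(dec$approximation, n)
  }
})

test_that("level deeper than the signal supports is rejected", {
  expect_error(decompose_mra(ppg_signal(rnorm(128), 100), level = 6), "too deep")
})

test_that("sub-Hz oscillations land in the top-level approximation", {
  tt <- (0:1023) / 100
  slow <- ppg_signal(sin(2 * pi * 0.3 * tt), fs = 100)
  dec <- decompose_mra(slow, level = 6)
  int <- interior(1024)
  frac <- sum(dec$approximation[int]^2) / sum(slow$samples[int]^2)
  expect_gt(frac, 0.9)

  mix <- ppg_signal(sin(2 * pi * 2 * tt) + sin(2 * pi * 0.2 * tt), fs = 100)
  bl <- estimate_baseline(decompose_mra(mix, level = 6))
  expect_gt(cor(bl$samples[int], sin(2 * pi * 0.2 * tt)[int]), 0.95)
})

test_that("baseline of trivial inputs is trivial", {
  dec <- decompose_mra(ppg_signal(rep(1.5, 512), 100))
  expect_equal(estimate_baseline(dec)$samples, rep(1.5, 512), tolerance = 1e-8)
  # zero signal -> zero baseline
  dec0 <- decompose_mra(ppg_signal(numeric(512), 100))
  expect_equal(estimate_baseline(dec0)$samples, numeric(512), tolerance = 1e-12)
  # truncated output length
  expect_length(estimate_baseline(dec, out_length = 100)$samples, 100)
  expect_error(estimate_baseline(dec, out_length = 1000), "out_length")
})

test_that("correct_signal subtracts pointwise and validates shapes", {
  s <- ppg_signal(rnorm(256), 100)
  expect_equal(correct_signal(s, s)$samples, numeric(256))
  short <- ppg_signal(rnorm(100), 100)
  expect_error(correct_signal(s, short), "lengths differ")
  other_fs <- ppg_signal(rnorm(256), 200)
  expect_error(correct_signal(s, other_fs), "sampling rates differ")
  out <- correct_baseline(ppg_signal(rnorm(1024), 100))
  expect_length(out$samples, 1024)
  expect_identical(out$fs, 100)
})

test_that("the raw -> baseline -> subtract path is linear", {
  set.seed(7)
  x <- rnorm(1024)
  y <- cumsum(rnorm(1024)) / 30
  a <- 2.5; b <- -0.7
  cx <- correct_baseline(ppg_signal(x, 100))$samples
  cy <- correct_baseline(ppg_signal(y, 100))$samples
  cxy <- correct_baseline(ppg_signal(a * x + b * y, 100))$samples
  expect_equal(cxy, a * cx + b * cy, tolerance = 1e-8)
})

test_that("drift is removed from a contaminated pulse train", {
  # drift amplitude twice the pulse amplitude, 0.2 Hz
  for (s in 1:3) {
    cfg <- synthetic_config(
      duration = 20, hr_mean = 72, hr_sd = 0, noise_sd = 0,
      drift = list(freqs = 0.2, amps = 2, rw_amp = 0),
      artifact_rate = 0, seed = s
    )
    rec <- generate_ppg(cfg)
    cor <- correct_baseline(rec$signal)
    int <- interior(length(cor$samples))
    cl <- rec$clean$samples[int]
    cc <- cor$samples[int]
    # correction removes the mean by construction; compare AC parts
    dev <- (cc - mean(cc)) - (cl - mean(cl))
    expect_lt(sqrt(mean(dev^2)) / sqrt(mean((cl - mean(cl))^2)), 0.15)
  }
})

test_that("correcting an already-corrected signal is a near no-op", {
  cfg <- synthetic_config(duration = 20, regime = "raising_hand", seed = 4)
  rec <- generate_ppg(cfg)
  c1 <- correct_baseline(rec$signal)
  c2 <- correct_baseline(c1)
  expect_lt(sqrt(mean((c2$samples - c1$samples)^2)) / sqrt(mean(c1$samples^2)),
            0.05)
})

test_that("correction strips the sub-0.5 Hz band of white noise", {
  set.seed(31)
  for (s in 1:3) {
    x <- rnorm(8192)
    cor <- correct_baseline(ppg_signal(x, 100))
    int <- interior(8192)
    ratio <- band_power(cor$samples[int], 100, 1e-9, 0.5) /
      band_power(x[int], 100, 1e-9, 0.5)
    expect_lt(ratio, 0.1)
  }
})
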