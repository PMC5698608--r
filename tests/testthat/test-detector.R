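test_that("adaptive threshold averages per-segment maxima", {
  expect_equal(compute_threshold(rep(3, 1000), t = 250), 1.5)  # half of a constant
  # 1..1024 with t = 256: segment maxima 256, 512, 768, 1024 -> mean 640
  expect_equal(compute_threshold(1:1024, t = 256), 320)
  # trailing remainder ignored: maxima 256, 512, 768 -> mean 512
  expect_equal(compute_threshold(1:1000, t = 256), 256)
  expect_error(compute_threshold(1:100, t = 256), "shorter than one segment")
})

test_that("modulus maxima extraction matches a neighbor-scan oracle", {
  expect_identical(nrow(extract_modulus_maxima(numeric(100), 4, 1)), 0L)
  tri <- c(numeric(10), seq(0, 2, length.out = 5), seq(2, 0, length.out = 5)[-1], numeric(10))
  mm <- extract_modulus_maxima(tri, 4, eps = 1)
  expect_identical(mm$index, 15L)
  expect_identical(mm$value, 2)

  set.seed(33)
  for (rep in 1:10) {
    W <- rnorm(256)
    eps <- runif(1, 0.1, 2)
    mm <- extract_modulus_maxima(W, 5, eps)
    expect_identical(mm$index, oracle_modulus_maxima(W, eps))
    expect_equal(mm$value, W[mm$index])
    expect_true(all(mm$magnitude > eps))
  }
})

test_that("cross-level retention keeps maxima persisting on both levels", {
  mk <- function(index, value) {
    data.frame(index = as.integer(index), level = 4L, value = value,
               magnitude = abs(value))
  }
  a <- mk(c(50, 120, 200), c(1, -2, 3))
  expect_identical(cross_level_retain(a, a, window = 0)$index, a$index)
  # distance 40 beyond a 16-sample window
  expect_identical(nrow(cross_level_retain(mk(100, 1), mk(140, 1), 16)), 0L)
  # same distance, opposite sign: no match either
  expect_identical(nrow(cross_level_retain(mk(100, 1), mk(110, -1), 16)), 0L)

  set.seed(44)
  for (rep in 1:20) {
    na <- sample(1:20, 1); nb <- sample(1:20, 1)
    a <- mk(sort(sample(1:500, na)), rnorm(na))
    b <- mk(sort(sample(1:500, nb)), rnorm(nb))
    got <- cross_level_retain(a, b, window = 16)
    expect_identical(got$index, a$index[oracle_cross_level(a, b, 16)])
  }
})

test_that("pair selection drops isolated maxima and resolves refractory clashes", {
  mk <- function(index, value) {
    data.frame(index = as.integer(index), level = 4L, value = value,
               magnitude = abs(value))
  }
  # a lone positive maximum cannot form a pair
  expect_identical(nrow(select_pairs(mk(100, 2), 300, 200, fs = 100)), 0L)
  # two pairs 11 samples apart at fs=100 (refractory 20 samples): larger wins
  m <- mk(c(100, 110, 112, 120), c(1, -1, 3, -3))
  got <- select_pairs(m, 300, 200, fs = 100)
  expect_identical(nrow(got), 1L)
  expect_identical(got$pos_index, 112L)
  expect_identical(got$amplitude, 6)
  # polarity order is not enforced: negative-first pairs work too
  got2 <- select_pairs(mk(c(100, 110), c(-2, 2)), 300, 200, fs = 100)
  expect_identical(nrow(got2), 1L)
  expect_true(got2$zero_crossing >= 100 && got2$zero_crossing <= 110)

  set.seed(55)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    idx <- sort(sample(1:400, n))
    val <- rnorm(n) * sample(c(1, 3), n, replace = TRUE)
    m <- mk(idx, val)
    got <- select_pairs(m, 300, 200, fs = 100)
    ora <- oracle_select_pairs(idx, val, ms_to_samples(300, 100),
                               ms_to_samples(200, 100))
    expect_identical(as.integer(got$zero_crossing), as.integer(ora$zero_crossing))
    expect_equal(got$amplitude, ora$amplitude)
  }
})

test_that("peaks refine to the signal argmax near the zero-crossing", {
  tt <- 0:999
  sig <- ppg_signal(exp(-((tt - 499)^2) / (2 * 25)), fs = 100)  # apex at index 500
  pr <- data.frame(pos_index = 490L, pos_value = 1, neg_index = 506L,
                   neg_value = -1, zero_crossing = 498L, amplitude = 2)
  expect_identical(locate_peaks(pr, sig, 100)$indices, 500L)
  # zero-crossing already at the maximum
  pr$zero_crossing <- 500L
  expect_identical(locate_peaks(pr, sig, 100)$indices, 500L)
  # two pairs refining to the same apex collapse to one peak
  two <- rbind(pr, transform(pr, zero_crossing = 503L))
  expect_identical(locate_peaks(two, sig, 100)$indices, 500L)
})

test_that("detector is exactly scale- and offset-invariant and deterministic", {
  rec <- generate_ppg(synthetic_config(duration = 20, regime = "raising_hand",
                                       seed = 12))
  base <- detect_peaks(rec$signal)
  expect_gt(length(base$indices), 10)
  for (alpha in c(0.1, 10)) {
    scaled <- ppg_signal(alpha * rec$signal$samples, rec$signal$fs)
    expect_identical(detect_peaks(scaled)$indices, base$indices)
  }
  shifted <- ppg_signal(rec$signal$samples + 0.5, rec$signal$fs)
  expect_identical(detect_peaks(shifted)$indices, base$indices)
  expect_identical(detect_peaks(rec$signal)$indices, base$indices)
})

test_that("no two detected peaks violate the refractory period", {
  for (s in 1:5) {
    rec <- generate_ppg(synthetic_config(duration = 30, regime = "walking",
                                         seed = s))
    pk <- detect_peaks(rec$signal)
    if (length(pk$indices) > 1) {
      expect_true(all(diff(pk$indices) >= ms_to_samples(200, 100)))
    }
    pkc <- detect_peaks(correct_baseline(rec$signal))
    expect_true(all(diff(pkc$indices) >= ms_to_samples(200, 100)))
  }
})

test_that("clean records are detected without error", {
  for (s in 1:3) {
    rec <- generate_ppg(clean_config(seed = s, duration = 30,
                                     hr_mean = 60 + 10 * s))
    pk <- detect_peaks(rec$signal)
    counts <- match_peaks(pk, rec$peaks, tolerance_ms = 50)
    expect_identical(unname(counts[c("FP", "FN")]), c(0L, 0L))
  }
})
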