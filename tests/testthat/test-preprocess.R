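test_that("moving average preserves DC, is identity at N = 1, checks bounds", {
  expect_equal(moving_average_filter(rep(2.5, 100), 7), rep(2.5, 100))
  x <- rnorm(50)
  expect_identical(moving_average_filter(x, 1), x)
  expect_error(moving_average_filter(x, 51), "longer")
  expect_length(moving_average_filter(x, 4), 50)
})

test_that("5-point moving average attenuates 50 Hz to the Dirichlet gain 0.2", {
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 50 * t)
  y <- moving_average_filter(x, 5)
  steady <- y[500:3500]
  amp <- (max(steady) - min(steady)) / 2
  expect_equal(amp, 0.2, tolerance = 0.005 / 0.2)
})

test_that("baseline removal kills drift, keeps the pass band, keeps R times", {
  fs <- 200
  t <- (0:11999) / fs
  drift <- sin(2 * pi * 0.3 * t)
  out <- remove_baseline(drift, fs)
  expect_lt(sqrt(mean(out[1000:11000]^2)), 0.1 * sqrt(mean(drift[1000:11000]^2)))

  tone <- sin(2 * pi * 1 * t)
  kept <- remove_baseline(tone, fs)
  gain <- stats::sd(kept[1000:11000]) / stats::sd(tone[1000:11000])
  expect_gt(20 * log10(gain), -1)

  expect_equal(remove_baseline(rep(0, 1000), fs), rep(0, 1000))

  sess <- noiseless_session()
  raw <- sess$record$samples
  hp <- remove_baseline(raw, 200)
  for (tb in sess$truth$r_times_s[c(10, 100, 200)]) {
    win <- round(tb * 200) + (-10:10)
    expect_equal(which.max(hp[win]), which.max(raw[win]))
  }
})

test_that("median-subtraction baseline removal leaves a zero-mean signal", {
  fs <- 200
  t <- (0:3999) / fs
  x <- 2 + sin(2 * pi * 0.2 * t)
  y <- remove_baseline(x, fs, method = "median")
  expect_lt(abs(mean(y)), 0.05)
  expect_length(y, length(x))
})

test_that("band-pass keeps 10 Hz, rejects 60 Hz and DC", {
  fs <- 200
  t <- (0:5999) / fs
  inb <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(inb, fs)
  expect_lt(abs(stats::sd(y[500:5500]) / stats::sd(inb[500:5500]) - 1), 0.05)

  outb <- sin(2 * pi * 60 * t)
  y2 <- bandpass_filter(outb, fs)
  expect_lt(stats::sd(y2[500:5500]) / stats::sd(outb[500:5500]), 0.1)

  y3 <- bandpass_filter(rep(1, 2000), fs)
  expect_lt(abs(mean(y3)), 0.01)
})

test_that("band-pass validates its design", {
  expect_error(bandpass_filter(rnorm(100), 200, 40, 0.5), "band edges")
  expect_error(bandpass_filter(rnorm(100), 200, 0.5, 120), "band edges")
  expect_error(bandpass_filter(rnorm(1000), 200, 1e-7, 40, order = 14),
               "order")
})

test_that("SNR follows the residual-power definition with caps", {
  x <- sin(2 * pi * 5 * (0:1999) / 200)
  expect_equal(estimate_snr(x, x), 99)
  expect_equal(estimate_snr(x, x * 0), -99)
  set.seed(21)
  noise <- rnorm(20000, sd = sqrt(0.5))
  s <- sin(2 * pi * 5 * (0:19999) / 200)
  expect_equal(estimate_snr(s + noise, s), 0, tolerance = 0.5)
  expect_error(estimate_snr(numeric(0), numeric(0)), "zero-length")
  expect_error(estimate_snr(1:5, 1:4), "lengths differ")
})

test_that("rejection rule: amplitude first, then SNR, else keep", {
  sess <- noiseless_session()
  raw <- sess$record$samples[1:6000]
  cleaned <- sess$cleaned[1:6000]
  expect_true(reject_segment(raw, cleaned)$keep)

  spiky <- raw; spiky[3000:3050] <- 10
  v <- reject_segment(spiky, cleaned)
  expect_false(v$keep); expect_equal(v$reason, "amplitude")

  set.seed(4)
  noisy <- cleaned + rnorm(6000, sd = stats::sd(cleaned) * 1.5)
  v2 <- reject_segment(noisy, cleaned)
  expect_false(v2$keep); expect_equal(v2$reason, "snr")
  expect_lt(v2$snr_db, 15)
})

test_that("segmentation counts follow floor(duration / window)", {
  rec <- ecg_record(rep(0.1, 600 * 200), 200, borg_score = 8)
  expect_length(segment_record(rec, 30), 20)
  expect_length(segment_record(rec, 120), 5)
  short <- ecg_record(rep(0.1, 29 * 200), 200, borg_score = 8)
  expect_warning(empty <- segment_record(short, 30), "shorter")
  expect_length(empty, 0)

  segs <- segment_record(rec, 30)
  expect_true(all(vapply(segs, function(s) length(s$samples), 0) == 6000))
  expect_true(all(vapply(segs, function(s) as.character(s$label), "") == "normal"))
  expect_equal(vapply(segs, function(s) s$segment_index, 0L), 0:19)
})

test_that("filtering never changes length or sampling grid", {
  for (n in c(777, 2000, 4801)) {
    x <- rnorm(n)
    expect_length(preprocess_signal(x, 200), n)
  }
})

test_that("the pipeline is near-idempotent where its gain is ~1", {
  fs <- 200
  t <- (0:7999) / fs
  x <- sin(2 * pi * 3 * t)
  once <- preprocess_signal(x, fs)
  twice <- preprocess_signal(once, fs)
  a1 <- stats::sd(once[1000:7000]); a2 <- stats::sd(twice[1000:7000])
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("default-noise rejection rate is moderate; zero-noise is zero", {
  prep <- small_prep()
  expect_gte(prep$rejection_rate, 0)
  expect_lte(prep$rejection_rate, 0.25)
  expect_true(all(!prep$report$keep == !is.na(prep$report$reason)))

  st0 <- generate_study(n_subjects = 1, n_days = 1, seed = 6,
                        noise = zero_noise_params())
  expect_equal(preprocess_study(st0)$rejection_rate, 0)
})
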