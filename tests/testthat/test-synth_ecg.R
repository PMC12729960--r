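test_that("zero-variance RR synthesis gives exactly constant intervals", {
  rr <- generate_rr_series(synth_class_params(60, 0, 1, 1), 60, seed = 1)
  expect_true(all(rr$rr_ms == 1000))
  expect_equal(diff(rr$times_s), rep(1, length(rr$rr_ms)), tolerance = 1e-12)
})

test_that("RR synthesis is a pure function of (params, duration, seed)", {
  p <- synth_class_params(60, 50, 1, 1)
  a <- generate_rr_series(p, 300, seed = 7)
  b <- generate_rr_series(p, 300, seed = 7)
  expect_identical(a, b)
  c2 <- generate_rr_series(p, 300, seed = 8)
  expect_false(identical(a, c2))
})

test_that("realized mean HR and SDNN track the targets", {
  for (hr in c(55, 80, 110)) {
    rr <- generate_rr_series(synth_class_params(hr, 40, 2, 0.8), 300,
                             seed = hr)
    expect_lt(abs(60000 / mean(rr$rr_ms) - hr), 3)
    sdnn <- sqrt(mean((rr$rr_ms - mean(rr$rr_ms))^2))
    expect_lt(abs(sdnn - 40) / 40, 0.15)
    expect_true(all(rr$rr_ms >= 300 & rr$rr_ms <= 2000))
    expect_true(all(diff(rr$times_s) > 0))
  }
})

test_that("the LF/HF ratio of the modulation is recovered from the PSD", {
  hi <- generate_rr_series(synth_class_params(60, 50, 4, 1), 300, seed = 3)
  lo <- generate_rr_series(synth_class_params(60, 50, 0.25, 1), 300, seed = 3)
  f_hi <- frequency_domain_features(hi)
  f_lo <- frequency_domain_features(lo)
  expect_gt(f_hi[["LF_HF"]], f_lo[["LF_HF"]])
  expect_gt(f_hi[["LF_HF"]], 1)
  expect_lt(f_lo[["LF_HF"]], 1)
})

test_that("noiseless synthesis places global maxima at the true R times", {
  rr <- structure(list(rr_ms = c(900, 900), times_s = c(0.5, 1.4, 2.3)),
                  class = "rr_series")
  out <- synthesize_ecg(rr, fs = 200, noise = zero_noise_params(),
                        duration_s = 3, borg_score = 7)
  x <- out$record$samples
  for (tb in out$truth$r_times_s) {
    idx <- which(x == max(x[round(tb * 200) + (-20:20)]))
    expect_lt(min(abs((idx - 1) / 200 - tb)), 0.006)
  }
  expect_equal(length(x), 600)
})

test_that("powerline noise appears as a dominant 50 Hz component", {
  rr <- generate_rr_series(synth_class_params(60, 0, 1, 1), 20, seed = 1)
  nz <- noise_params(0, 0.25, powerline_amp_mv = 0.1, white_sd_mv = 0,
                     artifact_rate_per_min = 0, artifact_amp_mv = 0)
  out <- synthesize_ecg(rr, fs = 200, noise = nz, seed = 4, duration_s = 20,
                        borg_score = 7)
  added <- out$record$samples - out$truth$clean
  sp <- Mod(stats::fft(added))^2
  freqs <- (seq_along(sp) - 1) * 200 / length(sp)
  half <- freqs <= 100 & freqs > 0
  expect_equal(freqs[half][which.max(sp[half])], 50, tolerance = 0.1)
})

test_that("artifacts only change the signal inside their windows", {
  rr <- generate_rr_series(synth_class_params(60, 0, 1, 1), 60, seed = 1)
  base <- noise_params(0.01, 0.25, 0.005, 0.003, artifact_rate_per_min = 0,
                       artifact_amp_mv = 0)
  art <- noise_params(0.01, 0.25, 0.005, 0.003, artifact_rate_per_min = 6,
                      artifact_amp_mv = 2)
  a <- synthesize_ecg(rr, fs = 200, noise = base, seed = 9, duration_s = 60,
                      borg_score = 7)
  b <- synthesize_ecg(rr, fs = 200, noise = art, seed = 9, duration_s = 60,
                      borg_score = 7)
  expect_false(is.null(b$truth$artifact_windows))
  t <- (seq_along(a$record$samples) - 1) / 200
  inside <- rep(FALSE, length(t))
  for (k in seq_len(nrow(b$truth$artifact_windows))) {
    inside <- inside | (t >= b$truth$artifact_windows[k, 1] - 1e-9 &
                        t <= b$truth$artifact_windows[k, 2] + 1e-9)
  }
  expect_identical(a$record$samples[!inside], b$record$samples[!inside])
  expect_false(identical(a$record$samples[inside], b$record$samples[inside]))
})

test_that("too-low sampling rates are rejected", {
  rr <- generate_rr_series(synth_class_params(60, 0, 1, 1), 10, seed = 1)
  expect_error(synthesize_ecg(rr, fs = 100, template = within(
    default_beat_template(), width <- width / 10)), "support")
})

test_that("study generation counts, determinism and class mix", {
  st <- generate_study(n_subjects = 2, n_days = 1, seed = 5)
  expect_equal(nrow(st$manifest), 6)
  expect_equal(length(st$records), 6)
  expect_true(all(vapply(st$records, function(r) r$duration_s, 0) == 600))

  st2 <- generate_study(n_subjects = 2, n_days = 1, seed = 5)
  expect_identical(st$manifest, st2$manifest)
  expect_identical(st$records, st2$records)

  big <- generate_study(n_subjects = 12, n_days = 14, seed = 1, signals = FALSE)
  counts <- table(vapply(big$truth, `[[`, "", "class"))[fatigue_levels()]
  rule <- default_session_class_rule()
  expected <- Reduce(`+`, rule) / 3 * 504
  expect_true(all(abs(counts - expected) / expected < 0.10))
})

test_that("written studies round-trip through the manifest and CSV files", {
  dir <- tempfile()
  st <- generate_study(n_subjects = 1, n_days = 1, seed = 31,
                       session_duration_s = 60, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_study(dir)
  expect_equal(nrow(back$manifest), 3)
  k <- back$manifest$key[1]
  expect_equal(back$records[[k]]$samples, st$records[[k]]$samples,
               tolerance = 1e-12)
  expect_equal(back$truth[[k]]$class, st$truth[[k]]$class)
})

test_that("HRV features recover generator parameters on noiseless data", {
  out <- noiseless_session()
  peaks <- pan_tompkins(out$cleaned, 200)
  rr <- rr_from_peaks(peaks)
  expect_lt(abs(60000 / mean(rr$rr_ms) - 60), 1)
  sdnn_det <- sqrt(mean((rr$rr_ms - mean(rr$rr_ms))^2))
  sdnn_true <- sqrt(mean((out$truth$rr_ms - mean(out$truth$rr_ms))^2))
  expect_lt(abs(sdnn_det - sdnn_true) / sdnn_true, 0.10)
})

test_that("session-level MeanRR separates the classes by > 2 pooled SDs", {
  # full study shape so the pooled-SD estimates are stable
  st <- generate_study(n_subjects = 12, n_days = 14, seed = 12,
                       waveforms = FALSE)
  cls <- vapply(st$truth, `[[`, "", "class")
  mean_rr <- vapply(st$truth, function(tr) mean(tr$rr_ms), 0)
  for (pair in list(c("normal", "slight"), c("slight", "fatigued"),
                    c("normal", "fatigued"))) {
    a <- mean_rr[cls == pair[1]]; b <- mean_rr[cls == pair[2]]
    expect_gte(min(length(a), length(b)), 2)
    pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
    expect_gt(abs(mean(a) - mean(b)) / pooled, 2)
  }
})
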