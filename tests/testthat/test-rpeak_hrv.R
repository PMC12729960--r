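test_that("Pan-Tompkins finds every beat of a clean 60 bpm recording", {
  rr <- generate_rr_series(synth_class_params(60, 30, 1, 1), 30, seed = 9)
  out <- synthesize_ecg(rr, fs = 200, noise = zero_noise_params(), seed = 10,
                        duration_s = 30, borg_score = 8)
  peaks <- pan_tompkins(preprocess_signal(out$record$samples, 200), 200)
  expect_gte(length(peaks$indices), 28)
  expect_lte(length(peaks$indices), 31)
  for (tp in peaks$times_s) {
    expect_lt(min(abs(out$truth$r_times_s - tp)), 0.020)
  }
  expect_named(peaks$stages, c("bandpassed", "derivative", "squared",
                               "integrated"))
  expect_true(all(lengths(peaks$stages) == length(out$record$samples)))
})

test_that("flat input yields no peaks with a warning", {
  expect_warning(p <- pan_tompkins(rep(0, 1000), 200), "flat")
  expect_length(p$indices, 0)
  expect_error(pan_tompkins(rnorm(100), 200), ">= 2 s")
})

test_that("the refractory period merges beats 150 ms apart", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  x <- numeric(length(t))
  beats <- c(1, 1.15, 2.2, 3.1, 4.0, 4.9, 5.8, 6.7, 7.6, 8.5)
  for (tb in beats) x <- x + exp(-(t - tb)^2 / (2 * 0.02^2))
  peaks <- pan_tompkins(x, fs)
  expect_equal(sum(peaks$times_s > 0.9 & peaks$times_s < 1.3), 1)
})

test_that("RR extraction gates unphysiologic intervals", {
  rr <- rr_from_peaks(c(0, 1.0, 2.0))
  expect_equal(rr$rr_ms, c(1000, 1000))
  expect_equal(attr(rr, "n_gated"), 0)

  gated <- rr_from_peaks(c(0, 1.0, 3.5))
  expect_equal(gated$rr_ms, 1000)
  expect_equal(attr(gated, "n_gated"), 1)

  expect_error(rr_from_peaks(c(1)), "insufficient beats")
})

test_that("detected RR statistics match generator ground truth", {
  sess <- noiseless_session()
  det <- rr_from_peaks(pan_tompkins(sess$cleaned, 200))
  expect_lt(abs(mean(det$rr_ms) - mean(sess$truth$rr_ms)) /
            mean(sess$truth$rr_ms), 0.01)
})

test_that("time-domain features on hand-checkable series", {
  f <- time_domain_features(c(800, 800, 800))
  expect_equal(unname(f), c(800, 0, 0, 0, 75))
  expect_equal(time_domain_features(c(800, 850))[["RMSSD"]], 50)
  expect_error(time_domain_features(c(800)), ">= 2")
})

test_that("time-domain and Poincare features match the naive-loop oracle", {
  set.seed(42)
  for (i in 1:50) {
    rr <- runif(sample(5:120, 1), 400, 1500)
    td <- time_domain_features(rr)
    expect_equal(unname(td), unname(oracle_time_domain(rr)),
                 tolerance = 1e-9)
    pc <- poincare_features(rr)
    expect_equal(unname(pc), unname(oracle_poincare(rr)), tolerance = 1e-9)
    sdnn <- td[["SDNN"]]
    if (pc[["SD1"]]^2 <= 2 * sdnn^2) {
      expect_equal(pc[["SD1"]]^2 + pc[["SD2"]]^2, 2 * sdnn^2,
                   tolerance = 1e-9 * max(1, sdnn^2))
    } else {
      expect_identical(pc[["SD2"]], 0)
    }
  }
})

test_that("Poincare features on degenerate and alternating series", {
  expect_equal(unname(poincare_features(rep(700, 10))), c(0, 0))
  alt <- rep(c(800, 850), 200)
  expect_equal(poincare_features(alt)[["SD1"]], 50 / sqrt(2), tolerance = 1e-3)
  expect_error(poincare_features(c(800, 850)), ">= 3")
})

test_that("spectral features localize pure-tone RR modulation", {
  mk <- function(freq) {
    t <- 0; rrs <- c()
    while (t < 300) {
      rr_k <- 1000 + 30 * sin(2 * pi * freq * t)
      rrs <- c(rrs, rr_k); t <- t + rr_k / 1000
    }
    structure(list(rr_ms = rrs, times_s = c(0, cumsum(rrs)) / 1000),
              class = "rr_series")
  }
  hf <- frequency_domain_features(mk(0.25))
  expect_gte(hf[["HF"]] / (hf[["LF"]] + hf[["HF"]]), 0.9)
  lf <- frequency_domain_features(mk(0.10))
  expect_gte(lf[["LF"]] / (lf[["LF"]] + lf[["HF"]]), 0.9)

  flat <- frequency_domain_features(rep(1000, 120))
  expect_lt(flat[["LF"]], 1e-6)
  expect_lt(flat[["HF"]], 1e-6)

  expect_error(frequency_domain_features(rep(1000, 10)), "span")
})

test_that("extract_features produces the 11-feature vector with provenance", {
  rr <- generate_rr_series(synth_class_params(60, 30, 1, 1), 30, seed = 15)
  out <- synthesize_ecg(rr, fs = 200, noise = zero_noise_params(), seed = 16,
                        duration_s = 30, borg_score = 8)
  seg <- ecg_segment(preprocess_signal(out$record$samples, 200), 200,
                     "normal", "s9", 3, "evening", 4)
  f <- extract_features(seg)
  expect_named(f, hrv_feature_names())
  expect_true(attr(f, "usable"))
  expect_equal(attr(f, "provenance")$subject_id, "s9")
  expect_lt(abs(f[["MeanHR"]] - 60), 1)
  f2 <- extract_features(seg)
  expect_identical(unclass(f), unclass(f2))

  zeros <- ecg_segment(rep(0, 6000), 200, "normal")
  expect_warning(fz <- extract_features(zeros), "unusable")
  expect_false(attr(fz, "usable"))
  expect_true(all(is.na(fz)))
})

test_that("beat detection quality holds across the small default-noise study", {
  st <- small_study()
  f1s <- vapply(names(st$records), function(key) {
    rec <- st$records[[key]]
    peaks <- pan_tompkins(preprocess_signal(rec$samples, rec$fs), rec$fs)
    detection_f1(peaks$times_s, st$truth[[key]]$r_times_s)[["f1"]]
  }, 0)
  expect_gte(mean(f1s), 0.95)
})

test_that("mean heart rate rises monotonically across synthetic classes", {
  ft <- small_features()$table
  m <- tapply(ft$MeanHR[ft$usable], ft$label[ft$usable], mean)
  expect_lt(m[["normal"]], m[["slight"]])
  expect_lt(m[["slight"]], m[["fatigued"]])
})
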