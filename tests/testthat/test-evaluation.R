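test_that("binary accuracies recompute from printed correct counts", {
  # non-fatigue vs slight: 128/143 and 170/192 correct
  cm <- matrix(c(128L, 22L, 15L, 170L), 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  expect_equal(round(100 * metrics_from_confusion(cm)$accuracy, 2), 88.96)
  # slight vs fatigued: 140/192 and 138/191 correct
  cm2 <- matrix(c(140L, 53L, 52L, 138L), 2,
                dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  expect_equal(round(100 * metrics_from_confusion(cm2)$accuracy, 2), 72.58)
})

test_that("metric edge cases: perfect diagonal, zero divisions, empty input", {
  perfect <- diag(c(5L, 7L, 9L))
  m <- metrics_from_confusion(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_f1, 1)

  cm <- matrix(c(3L, 2L, 0L, 0L), 2)  # nothing ever predicted as class 2
  expect_warning(z <- metrics_from_confusion(cm), "undefined")
  expect_equal(z$per_class$precision[2], 0)

  expect_error(metrics_from_confusion(matrix(0L, 2, 2)), "empty")
})

test_that("report metrics are recomputable from the stored confusion matrix", {
  set.seed(31)
  truth <- sample(fatigue_levels(), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth,
                 sample(fatigue_levels(), 200, replace = TRUE))
  rep <- eval_report(truth, pred, split = "toy")
  again <- metrics_from_confusion(rep$confusion)
  expect_identical(rep$accuracy, again$accuracy)
  expect_identical(rep$macro_f1, again$macro_f1)
  expect_equal(rep$n, 200)
})

test_that("stratified 20% floor split reproduces the study's test counts", {
  y <- rep(fatigue_levels(), times = c(719, 963, 958))
  tab <- data.frame(subject_id = "s", day = 1, session = "morning", label = y)
  plan <- split_segments(tab, "segment", test_fraction = 0.2, seed = 1)[[1]]
  counts <- table(factor(y[plan$test], levels = fatigue_levels()))
  expect_equal(unname(c(counts)), c(143L, 192L, 191L))
  expect_length(intersect(plan$train, plan$test), 0)
  expect_equal(sort(c(plan$train, plan$test)), seq_along(y))
})

test_that("session-wise splits never cut a session in half", {
  ft <- small_features()
  tab <- ft$table
  plan <- split_segments(tab, "session", seed = 2)[[1]]
  key <- paste(tab$subject_id, tab$day, tab$session)
  expect_length(intersect(key[plan$train], key[plan$test]), 0)
  expect_gt(length(plan$test), 0)
})

test_that("leave-2-subjects-out draws distinct reproducible subject pairs", {
  tab <- data.frame(subject_id = rep(sprintf("s%02d", 1:12), each = 4),
                    day = 1, session = "morning",
                    label = rep(fatigue_levels(), length.out = 48))
  plans <- split_segments(tab, "subject", seed = 3, repeats = 5, k = 2)
  descr <- vapply(plans, `[[`, "", "description")
  expect_length(unique(descr), 5)
  plans2 <- split_segments(tab, "subject", seed = 3, repeats = 5, k = 2)
  expect_identical(descr, vapply(plans2, `[[`, "", "description"))
  for (p in plans) {
    expect_length(unique(tab$subject_id[p$test]), 2)
    expect_length(intersect(tab$subject_id[p$train], tab$subject_id[p$test]), 0)
  }
  expect_error(split_segments(tab[tab$subject_id %in% c("s01", "s02"), ],
                              "subject", k = 2), "subjects")
})

test_that("k-fold partitions the data; leave-one-out has n folds", {
  d <- data.frame(x = rnorm(12))
  y <- rep(fatigue_levels(), 4)
  fit_const <- function(data, labels) {
    structure(list(lvl = names(which.max(table(labels)))), class = "dummy_clf")
  }
  assign("predict.dummy_clf",
         function(object, newdata, ...) {
           fatigue_factor(rep(object$lvl, nrow(newdata)))
         }, envir = globalenv())
  on.exit(rm("predict.dummy_clf", envir = globalenv()))
  cv <- kfold_cv(d, y, fit_const, k = 12, seed = 4)
  expect_length(cv$folds, 12)
  expect_true(all(vapply(cv$folds, `[[`, numeric(1), "n") == 1))
  expect_equal(sort(unlist(lapply(1:12, function(f) which(cv$fold_id == f)))),
               1:12)

  set.seed(9)
  d2 <- data.frame(x = rnorm(300))
  y2 <- rep(fatigue_levels(), 100)
  cv2 <- kfold_cv(d2, y2, fit_const, k = 10, seed = 5)
  expect_equal(cv2$accuracy_mean, 1 / 3, tolerance = 0.05 / (1 / 3))
})

test_that("McNemar closed forms and branch selection", {
  lab <- rep("normal", 10)
  a <- rep("normal", 10)                 # a always right
  b <- rep(c("normal", "slight"), c(0, 10))  # b always wrong
  r <- mcnemar_test(a, b, lab)
  expect_equal(r$b, 10); expect_equal(r$c, 0)
  expect_equal(r$p_value, 0.001953125)
  expect_match(r$method, "exact")

  # b = c = 5 is perfectly symmetric
  lab2 <- rep("normal", 10)
  a2 <- rep(c("normal", "slight"), each = 5)
  b2 <- rep(c("slight", "normal"), each = 5)
  r2 <- mcnemar_test(a2, b2, lab2)
  expect_equal(r2$b, 5); expect_equal(r2$c, 5)
  expect_equal(r2$p_value, 1)

  # large-sample branch: b = 40, c = 10
  lab3 <- rep("normal", 50)
  a3 <- c(rep("normal", 40), rep("slight", 10))
  b3 <- c(rep("slight", 40), rep("normal", 10))
  r3 <- mcnemar_test(a3, b3, lab3)
  expect_equal(r3$statistic, 16.82)
  expect_equal(r3$p_value, 4.1e-5, tolerance = 0.02)
  expect_match(r3$method, "chi-square")
  expect_error(mcnemar_test(a3[1:10], b3, lab3), "lengths")
})

test_that("the exact branch equals brute-force binomial enumeration", {
  for (n in 0:12) {
    for (b in 0:n) {
      cc <- n - b
      lab <- rep("normal", max(n, 1))
      pa <- pb <- lab
      if (b > 0) pb[seq_len(b)] <- "slight"
      if (cc > 0) pa[b + seq_len(cc)] <- "slight"
      r <- mcnemar_test(pa, pb, lab)
      # direct tail enumeration of X ~ Bin(n, 1/2)
      brute <- if (n == 0) 1 else {
        k <- min(b, cc)
        min(1, 2 * sum(choose(n, 0:k)) / 2^n)
      }
      expect_equal(r$p_value, brute, tolerance = 1e-12,
                   info = sprintf("b=%d c=%d", b, cc))
    }
  }
})

test_that("chi-square branch agrees with the stats-package McNemar test", {
  lab <- rep("normal", 80)
  a <- c(rep("normal", 50), rep("slight", 30))
  b <- c(rep("slight", 35), rep("normal", 45))
  r <- mcnemar_test(a, b, lab)
  tab <- table(a == lab, b == lab)
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, unname(ref$p.value))
})

test_that("duration sensitivity re-segments with a fixed session split", {
  st <- small_study()
  spec <- hrv_model_spec(function(f, l) fit_threshold_classifier(f, l, "MeanHR"))
  out <- duration_sensitivity(st, durations = c(30, 120), fit_fun = spec,
                              seed = 6)
  expect_equal(out$duration_s, c(30, 120))
  # 12 sessions x floor(600/d) segments, minus rejections
  expect_lte(out$n_segments[1], 12 * 20)
  expect_lte(out$n_segments[2], 12 * 5)
  expect_gt(out$n_segments[1], out$n_segments[2])
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
  expect_error(duration_sensitivity(st, durations = 1200, fit_fun = spec),
               "exceeds")
})

test_that("ablations share one split and serialize to a comparison table", {
  cfg <- tiny_cbl_config()
  toy <- toy_signal_set(20, len = cfg$input_len, fs = cfg$fs)
  tab <- data.frame(subject_id = "s", day = 1, session = "morning",
                    label = toy$y)
  plan <- split_segments(tab, "segment", seed = 7)[[1]]
  ab <- run_ablation(toy$x, toy$y, plan, config = cfg, seed = 8, epochs = 5,
                     lr = 1e-3)
  expect_named(ab$reports, c("full", "cnn_only", "bilstm_only"))
  ns <- vapply(ab$reports, `[[`, numeric(1), "n")
  expect_true(all(ns == length(plan$test)))
  expect_equal(nrow(ab$comparison), 3)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(ab$comparison, path, row.names = FALSE)
  expect_equal(nrow(utils::read.csv(path)), 3)
})
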