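test_that("layer arithmetic matches the architecture tables", {
  rep30 <- cbl_shape_report(cbl_config(window_s = 30))
  expect_match(rep30$output_shape[rep30$layer == "conv1d + ReLU + dropout"],
               "^976 x 32$")
  expect_match(rep30$output_shape[rep30$layer == "maxpool"], "^195 x 32$")

  rep20 <- cbl_shape_report(cbl_config(window_s = 20))
  expect_match(rep20$output_shape[rep20$layer == "conv1d + ReLU + dropout"],
               "^642 x 32$")
  expect_match(rep20$output_shape[rep20$layer == "maxpool"], "^128 x 32$")

  err <- tryCatch(cbl_config(window_s = 0.5), error = function(e) conditionMessage(e))
  expect_match(err, "100 samples")
  expect_match(err, "150")
})

test_that("softmax rows always sum to one", {
  cfg <- tiny_cbl_config()
  m <- build_cbl(cfg, seed = 1)
  set.seed(2)
  X <- matrix(rnorm(7 * cfg$input_len), 7)
  p <- predict(m, X, type = "prob")
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("a zeroed final layer predicts the uniform distribution", {
  cfg <- tiny_cbl_config()
  m <- build_cbl(cfg, seed = 1)
  m$weights$W2[] <- 0
  m$weights$b2[] <- 0
  p <- predict(m, matrix(rnorm(3 * cfg$input_len), 3), type = "prob")
  expect_equal(unname(p), matrix(1 / 3, 3, 3), tolerance = 1e-6)
})

test_that("predictions are batch-invariant", {
  cfg <- tiny_cbl_config()
  m <- build_cbl(cfg, seed = 4)
  set.seed(5)
  X <- matrix(rnorm(9 * cfg$input_len), 9)
  pb <- predict(m, X, type = "prob")
  p1 <- predict(m, X[4, , drop = FALSE], type = "prob")
  expect_equal(pb[4, ], p1[1, ], tolerance = 1e-5)
})

test_that("zero learning rate leaves weights untouched and loss constant", {
  cfg <- tiny_cbl_config(dropout = 0)
  toy <- toy_signal_set(10, len = cfg$input_len, fs = cfg$fs)
  m <- fit_cbl(toy$x, toy$y, cfg, seed = 6, epochs = 4, lr = 0,
               early_stop_acc = NULL)
  m0 <- build_cbl(cfg, seed = 6)
  expect_equal(m$weights$W1, m0$weights$W1, tolerance = 1e-12)
  expect_equal(stats::sd(m$history$loss), 0, tolerance = 1e-9)
  expect_equal(m$history$loss[1], log(3), tolerance = 0.2)
})

test_that("analytic gradients match finite differences on a tiny network", {
  for (type in c("full", "cnn_only", "bilstm_only")) {
    cfg <- tiny_cbl_config(type, dropout = 0)
    with_seed2(42, {
      X <- matrix(rnorm(4 * cfg$input_len), 4)
      y <- c(0L, 1L, 2L, 1L)
      w <- fatiguecg:::cbl_init_weights_cpp(unclass(cfg))
    })
    out <- fatiguecg:::cbl_loss_grad_cpp(X, y, w, unclass(cfg))
    eps <- 5e-3  # sized for single-precision forward evaluations
    with_seed2(1, {
      for (nm in c("W1", "W2", if (type != "bilstm_only") "Wc",
                   if (type != "cnn_only") c("W_l1f", "U_l2b"))) {
        g <- out$grad[[nm]]
        for (i in sample(length(w[[nm]]), 4)) {
          wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
          wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
          num <- (fatiguecg:::cbl_loss_grad_cpp(X, y, wp, unclass(cfg))$loss -
                  fatiguecg:::cbl_loss_grad_cpp(X, y, wm, unclass(cfg))$loss) /
                 (2 * eps)
          rel <- abs(g[i] - num) / max(1e-3, abs(g[i]) + abs(num))
          expect_lt(rel, 0.08)
        }
      }
    })
  }
})

test_that("training separates a three-class toy signal set", {
  cfg <- tiny_cbl_config()
  toy <- toy_signal_set(40, len = cfg$input_len, fs = cfg$fs)
  m <- fit_cbl(toy$x, toy$y, cfg, seed = 11, epochs = 60, lr = 3e-3)
  expect_gte(max(m$history$accuracy), 0.9)
  expect_gte(mean(predict(m, toy$x) == toy$y), 0.9)
})

test_that("fits are deterministic for a fixed seed", {
  cfg <- tiny_cbl_config()
  toy <- toy_signal_set(10, len = cfg$input_len, fs = cfg$fs)
  m1 <- fit_cbl(toy$x, toy$y, cfg, seed = 12, epochs = 5, lr = 1e-3)
  m2 <- fit_cbl(toy$x, toy$y, cfg, seed = 12, epochs = 5, lr = 1e-3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("training requires all three classes", {
  cfg <- tiny_cbl_config()
  toy <- toy_signal_set(6, len = cfg$input_len, fs = cfg$fs)
  keep <- toy$y != "fatigued"
  expect_error(fit_cbl(toy$x[keep, ], toy$y[keep], cfg), "classes")
})

test_that("ablation variants have the advertised structure and still learn", {
  cfg_cnn <- tiny_cbl_config("cnn_only")
  expect_false(any(grepl("BiLSTM", cbl_shape_report(cfg_cnn)$layer)))
  cfg_bi <- tiny_cbl_config("bilstm_only")
  expect_true(any(grepl("BiLSTM", cbl_shape_report(cfg_bi)$layer)))
  expect_false(any(grepl("conv", cbl_shape_report(cfg_bi)$layer)))

  toy <- toy_signal_set(30, len = cfg_cnn$input_len, fs = cfg_cnn$fs)
  for (cfg in list(cfg_cnn, cfg_bi)) {
    m <- fit_cbl(toy$x, toy$y, cfg, seed = 13, epochs = 80, lr = 3e-3)
    expect_gte(max(m$history$accuracy), 0.8)
  }
})

test_that("configurations survive serialization round-trips", {
  cfg <- build_variant("bilstm_only", cbl_config(window_s = 20))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back[order(names(back))],
               unclass(cfg)[order(names(unclass(cfg)))],
               tolerance = 1e-12)
})

test_that("full-batch loss is non-increasing early in training", {
  cfg <- tiny_cbl_config(dropout = 0)
  toy <- toy_signal_set(10, len = cfg$input_len, fs = cfg$fs)
  cfg$batch_size <- nrow(toy$x)
  ok <- 0
  for (seed in 1:20) {
    m <- fit_cbl(toy$x, toy$y, cfg,
                 seed = seed, epochs = 10, lr = 1e-4, early_stop_acc = NULL)
    if (all(diff(m$history$loss) <= 1e-5)) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("training history is recorded per epoch and plottable", {
  cfg <- tiny_cbl_config()
  toy <- toy_signal_set(8, len = cfg$input_len, fs = cfg$fs)
  m <- fit_cbl(toy$x, toy$y, cfg, seed = 2, epochs = 7, lr = 1e-3,
               early_stop_acc = NULL)
  expect_equal(nrow(m$history), 7)
  expect_named(m$history, c("epoch", "loss", "accuracy"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
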