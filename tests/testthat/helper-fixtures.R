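# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small default-noise study: 2 subjects x 2 days = 12 sessions
small_study <- function() {
  memo("small_study", function() generate_study(n_subjects = 2, n_days = 2, seed = 401))
}

small_prep <- function() {
  memo("small_prep", function() preprocess_study(small_study()))
}

small_features <- function() {
  memo("small_features", function() {
    segs <- small_prep()$segments
    list(segments = segs,
         table = extract_feature_table(segs),
         labels = fatiguecg:::segment_labels(segs))
  })
}

# one noiseless 300-s session at 60 bpm with ground truth
noiseless_session <- function() {
  memo("noiseless_session", function() {
    rr <- generate_rr_series(synth_class_params(60, 50, 1, 1), 300, seed = 77)
    out <- synthesize_ecg(rr, fs = 200, noise = zero_noise_params(), seed = 78,
                          duration_s = 300, borg_score = 8)
    out$cleaned <- preprocess_signal(out$record$samples, 200)
    out
  })
}

# tiny network configuration: fast to train, same code paths
tiny_cbl_config <- function(type = "full", dropout = 0.5) {
  cbl_config(fs = 20, window_s = 5, conv_filters = 4, conv_kernel = 20,
             conv_stride = 4, pool_size = 2, dropout = dropout,
             lstm_layers = 2, lstm_units = 6, fc_units = 8,
             batch_size = 30, type = type)
}

# three-class toy raw-signal set: class-dependent oscillation frequency
# class signal = oscillation frequency; frequencies sit below the Nyquist
# rate of the bilstm_only variant's block-averaged input (fs / 8)
toy_signal_set <- function(n_per_class = 30, len = 100, fs = 20, seed = 5) {
  with_seed2(seed, {
    freqs <- c(normal = 0.25, slight = 0.6, fatigued = 1.2)
    X <- NULL; y <- character(0)
    t <- (0:(len - 1)) / fs
    for (cl in names(freqs)) {
      for (i in seq_len(n_per_class)) {
        ph <- stats::runif(1, 0, 2 * pi)
        x <- sin(2 * pi * freqs[[cl]] * t + ph) + stats::rnorm(len, 0, 0.1)
        X <- rbind(X, x)
        y <- c(y, cl)
      }
    }
    list(x = unname(X), y = fatigue_factor(y))
  })
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# naive-loop HRV oracles, independent of the package implementations
oracle_time_domain <- function(rr) {
  n <- length(rr)
  mean_rr <- sum(rr) / n
  sdnn <- sqrt(sum((rr - mean_rr)^2) / n)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  rmssd <- sqrt(sum(d^2) / (n - 1))
  pnn50 <- 100 * sum(abs(d) > 50) / (n - 1)
  c(MeanRR = mean_rr, SDNN = sdnn, RMSSD = rmssd, pNN50 = pnn50,
    MeanHR = 60000 / mean_rr)
}

oracle_poincare <- function(rr) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  md <- sum(d) / (n - 1)
  sd1 <- sqrt(sum((d - md)^2) / (n - 1)) / sqrt(2)
  mean_rr <- sum(rr) / n
  sdnn2 <- sum((rr - mean_rr)^2) / n
  c(SD1 = sd1, SD2 = sqrt(max(0, 2 * sdnn2 - sd1^2)))
}
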