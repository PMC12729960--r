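#' Configuration of the CNN-BiLSTM fatigue classifier
#'
#' Architecture and training hyper-parameters of the hybrid model: a 1-D
#' convolutional block (32 filters, kernel 150 samples, stride 6, ReLU,
#' dropout 0.5, max-pool 5) followed by two bidirectional LSTM layers of 50
#' units, a ReLU fully connected layer, dropout and a 3-way softmax; trained
#' with Adam on cross-entropy at learning rate 1e-4 in batches of 120.
#'
#' @param fs sampling rate (Hz) of the input segments.
#' @param window_s segment duration (s); input length is
#'   \code{round(fs * window_s)} samples and must be at least the kernel.
#' @param conv_filters,conv_kernel,conv_stride convolution block geometry.
#' @param pool_size max-pooling length.
#' @param dropout dropout probability in \code{[0, 1)}, applied after the
#'   convolution and after the fully connected layer.
#' @param lstm_layers,lstm_units recurrent block geometry (units per
#'   direction).
#' @param lstm_subsample optional temporal block-average subsampling factor
#'   applied before the first BiLSTM (default 1 = off); an interpretation of
#'   a recurrent "stride" setting, see the package vignette.
#' @param fc_units width of the fully connected layer.
#' @param n_classes number of output classes (3).
#' @param lr,batch_size,epochs Adam learning rate, batch size and maximum
#'   epoch count. The default 200 epochs is the desk-scale setting; set 2000
#'   for full-scale training.
#' @param type \code{"full"}, or the ablation variants \code{"cnn_only"}
#'   (convolution block, flatten, FC head) and \code{"bilstm_only"}
#'   (block-averaged raw sequence into the recurrent block).
#' @return Object of class \code{cbl_config}.
#' @export
cbl_config <- function(fs = 200, window_s = 30, conv_filters = 32,
                       conv_kernel = 150, conv_stride = 6, pool_size = 5,
                       dropout = 0.5, lstm_layers = 2, lstm_units = 50,
                       lstm_subsample = 1, fc_units = 64, n_classes = 3,
                       lr = 1e-4, batch_size = 120, epochs = 200,
                       type = c("full", "cnn_only", "bilstm_only")) {
  type <- match.arg(type)
  input_len <- round(fs * window_s)
  if (dropout < 0 || dropout >= 1) stop_fcg("dropout must be in [0, 1)")
  if (n_classes != 3) stop_fcg("the fatigue classifier is 3-class")
  if (type != "bilstm_only" && conv_kernel > input_len) {
    stop_fcg("window of %d samples (%g s at %g Hz) shorter than kernel %d",
             input_len, window_s, fs, conv_kernel)
  }
  cfg <- list(fs = fs, window_s = window_s, input_len = input_len,
              conv_filters = conv_filters, conv_kernel = conv_kernel,
              conv_stride = conv_stride, pool_size = pool_size,
              dropout = dropout, lstm_layers = lstm_layers,
              lstm_units = lstm_units, lstm_subsample = lstm_subsample,
              fc_units = fc_units, n_classes = n_classes, lr = lr,
              batch_size = batch_size, epochs = epochs, type = type,
              bilstm_downsample = conv_stride * pool_size)
  class(cfg) <- "cbl_config"
  cfg
}

#' Layer-by-layer shape report
#'
#' Output dimensions of every layer for a given configuration, e.g. at
#' 30 s and 200 Hz the convolution yields
#' \code{floor((6000 - 150) / 6) + 1 = 976} steps and pooling
#' \code{floor(976 / 5) = 195}.
#'
#' @param config a \code{\link{cbl_config}}.
#' @return data.frame with columns \code{layer} and \code{output_shape}.
#' @export
cbl_shape_report <- function(config) {
  stopifnot(inherits(config, "cbl_config"))
  L <- config$input_len
  rows <- list(c("input", sprintf("%d x 1", L)))
  if (config$type != "bilstm_only") {
    conv_len <- floor((L - config$conv_kernel) / config$conv_stride) + 1
    pool_len <- floor(conv_len / config$pool_size)
    rows <- c(rows, list(
      c("conv1d + ReLU + dropout", sprintf("%d x %d", conv_len, config$conv_filters)),
      c("maxpool", sprintf("%d x %d", pool_len, config$conv_filters))))
    seq_len <- pool_len
    seq_dim <- config$conv_filters
  } else {
    seq_len <- floor(L / config$bilstm_downsample)
    seq_dim <- 1
    rows <- c(rows, list(c("block-average downsample",
                           sprintf("%d x 1", seq_len))))
  }
  if (config$type != "cnn_only") {
    if (config$lstm_subsample > 1) {
      seq_len <- floor(seq_len / config$lstm_subsample)
      rows <- c(rows, list(c("temporal subsample", sprintf("%d x %d", seq_len, seq_dim))))
    }
    for (l in seq_len(config$lstm_layers)) {
      rows <- c(rows, list(c(sprintf("BiLSTM%d", l),
                             sprintf("%d x %d", seq_len, 2 * config$lstm_units))))
    }
    rows <- c(rows, list(c("final states", sprintf("%d", 2 * config$lstm_units))))
  } else {
    rows <- c(rows, list(c("flatten", sprintf("%d", seq_len * seq_dim))))
  }
  rows <- c(rows, list(c("FC + ReLU + dropout", sprintf("%d", config$fc_units)),
                       c("softmax", sprintf("%d", config$n_classes))))
  data.frame(layer = vapply(rows, `[`, "", 1),
             output_shape = vapply(rows, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' @export
print.cbl_config <- function(x, ...) {
  cat(sprintf("<cbl_config> %s: %g s @ %g Hz, lr %g, batch %d, epochs %d\n",
              x$type, x$window_s, x$fs, x$lr, x$batch_size, x$epochs))
  print(cbl_shape_report(x), row.names = FALSE)
  invisible(x)
}

#' Build an untrained CNN-BiLSTM model
#'
#' Initializes weights (Glorot-uniform, forget-gate biases 1) from the
#' current RNG stream (or \code{seed}) and attaches the shape report.
#'
#' @param config a \code{\link{cbl_config}}.
#' @param seed integer seed or \code{NULL}.
#' @return Object of class \code{cbl_model} (untrained).
#' @export
build_cbl <- function(config = cbl_config(), seed = NULL) {
  stopifnot(inherits(config, "cbl_config"))
  weights <- with_seed(seed, cbl_init_weights_cpp(unclass(config)))
  structure(list(config = config, weights = weights, trained = FALSE,
                 history = NULL, classes = fatigue_levels(),
                 shape = cbl_shape_report(config)),
            class = "cbl_model")
}

#' Build an ablation variant configuration
#'
#' @param kind \code{"cnn_only"} or \code{"bilstm_only"}.
#' @param config base \code{\link{cbl_config}}.
#' @return A \code{cbl_config} of the requested variant.
#' @export
build_variant <- function(kind = c("cnn_only", "bilstm_only"),
                          config = cbl_config()) {
  kind <- match.arg(kind)
  config$type <- kind
  config
}

# stack segments into an (n x L) matrix with per-segment z-normalization
segments_to_matrix <- function(segments, input_len) {
  X <- matrix(0, nrow = length(segments), ncol = input_len)
  for (i in seq_along(segments)) {
    s <- if (inherits(segments[[i]], "ecg_segment")) segments[[i]]$samples else segments[[i]]
    if (length(s) != input_len) {
      stop_fcg("segment %d has %d samples; the model expects %d",
               i, length(s), input_len)
    }
    sdv <- sd_pop(s)
    X[i, ] <- if (sdv > 0) (s - mean(s)) / sdv else 0
  }
  X
}

segment_labels <- function(segments) {
  fatigue_factor(vapply(segments, function(s) as.character(s$label), ""))
}

#' Fit the CNN-BiLSTM fatigue classifier
#'
#' Trains the model of \code{config} on raw preprocessed ECG segments
#' (per-segment standardized to zero mean and unit variance internally) by
#' minimizing cross-entropy with Adam. Training history (per-epoch loss and
#' accuracy) is recorded. Deterministic for a fixed seed and build.
#'
#' @param x list of \code{ecg_segment} (or numeric matrix, one segment per
#'   row of length \code{config$input_len}).
#' @param y fatigue labels (taken from the segments when \code{x} is a
#'   segment list and \code{y} is \code{NULL}).
#' @param config a \code{\link{cbl_config}}.
#' @param seed integer seed (weights, dropout and shuffling all derive from
#'   it).
#' @param epochs,lr optional overrides of the config values.
#' @param early_stop_acc,early_stop_patience stop early once training
#'   accuracy has reached \code{early_stop_acc} for
#'   \code{early_stop_patience} consecutive epochs; set
#'   \code{early_stop_acc = NULL} to disable.
#' @param clip_norm global gradient-norm clipping bound (stabilizes training
#'   at desk-scale learning rates); \code{0} disables clipping.
#' @param finetune_lr,finetune_epochs optional second training phase at a
#'   lower learning rate, warm-started from the first phase (runs after
#'   early stopping); \code{NULL} disables it.
#' @param ema_decay per-step exponential moving-average decay for the
#'   evaluation weights (0 = report the raw final weights). Averaging the
#'   last optimizer steps removes endpoint noise from dropout and small
#'   batches without changing the optimization itself.
#' @return A trained \code{cbl_model} with \code{history} (data.frame of
#'   per-epoch loss and accuracy).
#' @export
fit_cbl <- function(x, y = NULL, config = cbl_config(), seed = 1,
                    epochs = NULL, lr = NULL, early_stop_acc = 0.995,
                    early_stop_patience = 3, clip_norm = 1.0,
                    finetune_lr = NULL, finetune_epochs = 12,
                    ema_decay = 0.995) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(y)) y <- segment_labels(x)
    x <- segments_to_matrix(x, config$input_len)
  }
  y <- fatigue_factor(y)
  if (nlevels(droplevels(y)) < config$n_classes) {
    stop_fcg("training labels cover %d of %d classes",
             nlevels(droplevels(y)), config$n_classes)
  }
  if (is.null(epochs)) epochs <- config$epochs
  if (is.null(lr)) lr <- config$lr
  if (is.null(early_stop_acc)) early_stop_acc <- 2  # unreachable: disabled
  fit <- with_seed(seed, {
    w0 <- cbl_init_weights_cpp(unclass(config))
    f1 <- cbl_train_cpp(x, as.integer(y) - 1L, w0, unclass(config),
                        lr = lr, batch = config$batch_size, epochs = epochs,
                        early_stop_acc = early_stop_acc,
                        early_stop_patience = early_stop_patience,
                        clip_norm = clip_norm, ema_decay = ema_decay)
    if (!is.null(finetune_lr) && finetune_epochs > 0) {
      f2 <- cbl_train_cpp(x, as.integer(y) - 1L, f1$raw_weights,
                          unclass(config),
                          lr = finetune_lr, batch = config$batch_size,
                          epochs = finetune_epochs, early_stop_acc = 2,
                          early_stop_patience = early_stop_patience,
                          clip_norm = clip_norm, ema_decay = ema_decay)
      f1 <- list(weights = f2$weights, loss = c(f1$loss, f2$loss),
                 accuracy = c(f1$accuracy, f2$accuracy))
    }
    f1
  })
  structure(list(config = config, weights = fit$weights, trained = TRUE,
                 history = data.frame(epoch = seq_along(fit$loss),
                                      loss = fit$loss,
                                      accuracy = fit$accuracy),
                 classes = fatigue_levels(), seed = seed,
                 shape = cbl_shape_report(config)),
            class = "cbl_model")
}

#' Predict fatigue classes or probabilities
#'
#' @param object a \code{cbl_model}.
#' @param newdata list of segments or numeric matrix (rows = segments).
#' @param type \code{"class"} (argmax; ties resolve to the lower ordinal
#'   class) or \code{"prob"}.
#' @param ... unused.
#' @return Factor of classes, or an n x 3 probability matrix whose rows sum
#'   to 1.
#' @export
predict.cbl_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.matrix(newdata)) {
    newdata <- segments_to_matrix(newdata, object$config$input_len)
  }
  if (ncol(newdata) != object$config$input_len) {
    stop_fcg("input has %d samples per segment; the model expects %d",
             ncol(newdata), object$config$input_len)
  }
  probs <- cbl_predict_cpp(newdata, object$weights, unclass(object$config))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  # ties resolve to the lower ordinal class via which.max's first-match rule
  fatigue_factor(object$classes[apply(probs, 1, which.max)])
}

#' @export
print.cbl_model <- function(x, ...) {
  cat(sprintf("<cbl_model> %s, %s\n", x$config$type,
              if (x$trained) sprintf("trained %d epochs (final acc %.3f)",
                                     nrow(x$history),
                                     x$history$accuracy[nrow(x$history)])
              else "untrained"))
  invisible(x)
}

#' @export
summary.cbl_model <- function(object, ...) {
  print(object)
  print(object$shape, row.names = FALSE)
  n_par <- sum(vapply(object$weights, function(w) {
    if (is.matrix(w)) length(w) else 0L
  }, integer(1)))
  cat(sprintf("parameters: %d\n", n_par))
  invisible(object)
}

#' Plot the training history
#' @param x a trained \code{cbl_model}.
#' @param ... forwarded to \code{plot}.
#' @export
plot.cbl_model <- function(x, ...) {
  if (is.null(x$history)) stop_fcg("model is untrained")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "l", xlab = "epoch",
       ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
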