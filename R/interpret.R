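#' 1-D Grad-CAM for the CNN-BiLSTM model
#'
#' Gradient-weighted class activation mapping on the (single) convolutional
#' block: channel weights are the temporal mean of the target-class logit's
#' gradients w.r.t. the post-ReLU feature maps, the CAM is the rectified
#' channel-weighted sum, linearly interpolated from conv-map length to input
#' length and min-max normalized to \code{[0, 1]} (an all-zero CAM stays
#' all-zero).
#'
#' @param model a trained \code{cbl_model} with a convolutional block
#'   (\code{full} or \code{cnn_only}; \code{bilstm_only} is unsupported).
#' @param segment an \code{ecg_segment}, numeric vector, or single-row
#'   matrix.
#' @param target_class class whose evidence is localized (default the
#'   model's predicted class).
#' @return Object of class \code{cam_curve}: \code{relevance} (length =
#'   input samples), \code{target_class}, \code{conv_cam} (unnormalized
#'   conv-resolution CAM), \code{provenance}.
#' @export
grad_cam_1d <- function(model, segment, target_class = NULL) {
  stopifnot(inherits(model, "cbl_model"))
  if (model$config$type == "bilstm_only") {
    stop_fcg("Grad-CAM requires a convolutional block; `bilstm_only` has none")
  }
  prov <- NULL
  if (inherits(segment, "ecg_segment")) {
    prov <- segment[c("subject_id", "day", "session", "segment_index")]
    segment <- list(segment)
  } else if (is.numeric(segment) && is.null(dim(segment))) {
    segment <- matrix(segment, nrow = 1)
  }
  X <- if (is.matrix(segment)) {
    t(apply(segment, 1, function(r) {
      s <- sd_pop(r); if (s > 0) (r - mean(r)) / s else r * 0
    }))
  } else segments_to_matrix(segment, model$config$input_len)
  if (nrow(X) != 1) stop_fcg("grad_cam_1d expects a single segment")
  if (is.null(target_class)) {
    target_class <- as.character(predict(model, X))
  }
  tc <- match(as.character(target_class), fatigue_levels())
  if (is.na(tc)) stop_fcg("unknown target class %s", target_class)
  out <- cbl_gradcam_cpp(X, model$weights, unclass(model$config), tc - 1L)
  cam <- as.numeric(out$cam[1, ])
  L <- model$config$input_len
  # conv step t covers input samples [t * stride, t * stride + kernel);
  # map each conv position to the centre of its receptive field
  centers <- (seq_along(cam) - 1) * model$config$conv_stride +
    (model$config$conv_kernel + 1) / 2
  rel <- stats::approx(centers, cam, xout = seq_len(L), rule = 2)$y
  if (max(rel) > 0) rel <- rel / max(rel)
  structure(list(relevance = rel, target_class = fatigue_levels()[tc],
                 conv_cam = cam, provenance = prov),
            class = "cam_curve")
}

#' @export
print.cam_curve <- function(x, ...) {
  cat(sprintf("<cam_curve> class %s, %d samples, activation area %.1f%%\n",
              x$target_class, length(x$relevance), activation_area(x)))
  invisible(x)
}

#' Plot a CAM curve
#' @param x a \code{cam_curve}.
#' @param fs sampling rate for the time axis (Hz).
#' @param ... forwarded to \code{plot}.
#' @export
plot.cam_curve <- function(x, fs = 200, ...) {
  plot((seq_along(x$relevance) - 1) / fs, x$relevance, type = "l",
       xlab = "time (s)", ylab = "relevance", ylim = c(0, 1), ...)
  invisible(x)
}

#' Activation area of a CAM curve
#'
#' Percentage of samples whose relevance reaches \code{rel_threshold} times
#' the curve maximum. An all-zero CAM has area 0.
#'
#' @param cam a \code{cam_curve} or numeric relevance vector.
#' @param rel_threshold relative threshold in \code{(0, 1]}.
#' @return Percentage in \code{[0, 100]}.
#' @export
activation_area <- function(cam, rel_threshold = 0.5) {
  if (!(rel_threshold > 0 && rel_threshold <= 1)) {
    stop_fcg("rel_threshold must be in (0, 1], got %g", rel_threshold)
  }
  v <- if (inherits(cam, "cam_curve")) cam$relevance else as.numeric(cam)
  if (!length(v)) stop_fcg("empty CAM")
  m <- max(v)
  if (m <= 0) return(0)
  100 * mean(v >= rel_threshold * m)
}

#' Relative increase between two activation areas
#'
#' @param reference baseline area (percent).
#' @param value comparison area (percent).
#' @return Relative increase in percent:
#'   \code{100 (value - reference) / reference}.
#' @export
relative_increase <- function(reference, value) {
  if (reference <= 0) stop_fcg("reference area must be positive")
  100 * (value - reference) / reference
}

#' Class-mean activation areas over a dataset
#'
#' Computes each segment's Grad-CAM for its true class and averages the
#' activation areas per class, reporting whether the areas expand with
#' fatigue (normal <= slight <= fatigued).
#'
#' @param model a trained \code{cbl_model} with a conv block.
#' @param segments list of \code{ecg_segment} (or matrix rows).
#' @param labels true classes (taken from segments if \code{NULL}).
#' @param rel_threshold see \code{\link{activation_area}}.
#' @return List of class \code{activation_summary}: \code{areas} (named
#'   per-class means), \code{n} (per-class counts), \code{ordered}
#'   (logical), \code{relative_increase_pct} (vs the normal class).
#' @export
class_mean_activation_area <- function(model, segments, labels = NULL,
                                       rel_threshold = 0.5) {
  if (is.null(labels)) labels <- segment_labels(segments)
  labels <- fatigue_factor(labels)
  n_seg <- if (is.matrix(segments)) nrow(segments) else length(segments)
  stopifnot(n_seg == length(labels))
  areas <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    seg <- if (is.matrix(segments)) segments[i, ] else segments[[i]]
    cam <- grad_cam_1d(model, seg, target_class = as.character(labels[i]))
    areas[i] <- activation_area(cam, rel_threshold)
  }
  counts <- table(labels)
  empty <- names(counts)[counts == 0]
  if (length(empty)) warning("empty class(es) excluded: ", paste(empty, collapse = ", "))
  mean_area <- tapply(areas, labels, mean)
  present <- !is.na(mean_area)
  ordered <- all(diff(mean_area[present]) >= 0)
  rel_inc <- if (!is.na(mean_area["normal"]) && mean_area["normal"] > 0) {
    vapply(mean_area, function(a) relative_increase(mean_area[["normal"]], a),
           numeric(1))
  } else rep(NA_real_, length(mean_area))
  structure(list(areas = mean_area, n = as.integer(counts), ordered = ordered,
                 relative_increase_pct = rel_inc, per_segment = areas),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  for (cl in names(x$areas)) {
    cat(sprintf("  %-8s mean activation area %5.2f%% (%+.1f%% vs normal)\n",
                cl, x$areas[[cl]], x$relative_increase_pct[[cl]]))
  }
  cat(if (x$ordered) "  areas expand with fatigue (normal <= slight <= fatigued)\n"
      else "  areas do not expand monotonically with fatigue\n")
  invisible(x)
}
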