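#' Confusion matrix (rows = true, columns = predicted)
#'
#' @param truth,pred equal-length label vectors.
#' @param levels class levels (default the three fatigue classes; pass two
#'   levels for a binary task).
#' @return Integer matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(truth, pred, levels = fatigue_levels()) {
  if (length(truth) != length(pred)) stop_fcg("length mismatch")
  cm <- table(factor(as.character(truth), levels = levels),
              factor(as.character(pred), levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): accuracy \code{(TP+TN)/(TP+TN+FP+FN)}, precision
#' \code{TP/(TP+FP)}, recall \code{TP/(TP+FN)} and
#' \code{F1 = 2PR/(P+R)}; macro values are unweighted means over classes.
#' Overall accuracy is the diagonal fraction. Divisions by zero yield 0 with
#' a warning.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @return List: \code{accuracy}, \code{macro_precision},
#'   \code{macro_recall}, \code{macro_f1}, \code{per_class} (data.frame).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  if (is.null(dim(cm)) || nrow(cm) != ncol(cm) || nrow(cm) < 2) {
    stop_fcg("confusion matrix must be square, >= 2x2")
  }
  n <- sum(cm)
  if (n == 0) stop_fcg("empty confusion matrix")
  k <- nrow(cm)
  if (is.null(rownames(cm))) rownames(cm) <- as.character(seq_len(k))
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (0/0); reported as 0", what)); 0 }
    else num / den
  }
  per <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    prec <- safe_div(tp, tp + fp, "precision")
    rec <- safe_div(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = rownames(cm)[i], accuracy = (tp + tn) / n,
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(diag(cm)) / n,
       macro_precision = mean(per$precision),
       macro_recall = mean(per$recall),
       macro_f1 = mean(per$f1),
       per_class = per)
}

#' Build an evaluation report
#'
#' @param truth,pred label vectors over the same test set.
#' @param split description of the split used.
#' @param levels class levels.
#' @return Object of class \code{eval_report}: confusion matrix, all metrics
#'   (recomputable from the stored matrix) and the split descriptor.
#' @export
eval_report <- function(truth, pred, split = "unspecified",
                        levels = fatigue_levels()) {
  cm <- confusion_matrix(truth, pred, levels)
  structure(c(list(confusion = cm, split = split, n = sum(cm)),
              metrics_from_confusion(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: n = %d, accuracy %.3f, macro F1 %.3f\n",
              x$split, x$n, x$accuracy, x$macro_f1))
  print(unclass(x$confusion))
  invisible(x)
}

#' Train/test split plans for a segment table
#'
#' Three leakage-control strategies over a table with provenance columns
#' (\code{subject_id}, \code{day}, \code{session}) and \code{label}:
#' \describe{
#'   \item{segment}{per-class stratified random split; per-class test count
#'     is \code{floor(test_fraction x class size)}.}
#'   \item{session}{whole recording sessions are assigned to train or test
#'     (stratified by session label), so no session's segments straddle the
#'     split.}
#'   \item{subject}{leave-\code{k}-subjects-out; \code{repeats} independent
#'     draws of \code{k} test subjects without repetition of test sets.}
#' }
#'
#' @param seg_table data.frame of segments (one row per segment).
#' @param strategy \code{"segment"}, \code{"session"} or \code{"subject"}.
#' @param test_fraction test share for segment/session strategies.
#' @param seed RNG seed; all draws are seed-deterministic.
#' @param repeats number of independent plans (subject strategy).
#' @param k test subjects per plan (subject strategy).
#' @return List of split plans, each of class \code{split_plan} with integer
#'   \code{train} and \code{test} row indices and a \code{description}.
#' @export
split_segments <- function(seg_table, strategy = c("segment", "session", "subject"),
                           test_fraction = 0.2, seed = 1, repeats = 1, k = 2) {
  strategy <- match.arg(strategy)
  y <- fatigue_factor(seg_table$label)
  n <- nrow(seg_table)
  plans <- with_seed(seed, {
    if (strategy == "segment") {
      lapply(seq_len(repeats), function(r) {
        test <- integer(0)
        for (cl in fatigue_levels()) {
          rows <- which(y == cl)
          n_test <- floor(test_fraction * length(rows))
          test <- c(test, sample(rows, n_test))
        }
        new_split(setdiff(seq_len(n), test), sort(test),
                  sprintf("segment-level stratified %d%% test (repeat %d)",
                          round(100 * test_fraction), r))
      })
    } else if (strategy == "session") {
      key <- paste(seg_table$subject_id, seg_table$day, seg_table$session, sep = "\r")
      sess <- !duplicated(key)
      sess_key <- key[sess]
      sess_lab <- y[sess]
      lapply(seq_len(repeats), function(r) {
        test_sessions <- character(0)
        for (cl in fatigue_levels()) {
          ks <- sess_key[sess_lab == cl]
          n_test <- floor(test_fraction * length(ks))
          test_sessions <- c(test_sessions, sample(ks, n_test))
        }
        test <- which(key %in% test_sessions)
        new_split(setdiff(seq_len(n), test), test,
                  sprintf("session-wise %d%% test (repeat %d)",
                          round(100 * test_fraction), r))
      })
    } else {
      subjects <- unique(seg_table$subject_id)
      if (length(subjects) <= k) {
        stop_fcg("need more than k = %d subjects, have %d", k, length(subjects))
      }
      combos <- list()
      lapply(seq_len(repeats), function(r) {
        repeat {
          test_sub <- sort(sample(subjects, k))
          tag <- paste(test_sub, collapse = "+")
          if (!tag %in% names(combos) ||
              length(combos) >= choose(length(subjects), k)) break
        }
        combos[[paste(test_sub, collapse = "+")]] <<- TRUE
        test <- which(seg_table$subject_id %in% test_sub)
        new_split(setdiff(seq_len(n), test), test,
                  sprintf("leave-%d-subjects-out (%s)", k,
                          paste(test_sub, collapse = ", ")))
      })
    }
  })
  plans
}

new_split <- function(train, test, description) {
  if (length(intersect(train, test))) stop_fcg("split leakage: train and test overlap")
  structure(list(train = train, test = test, description = description),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d test\n", x$description,
              length(x$train), length(x$test)))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' @param data data.frame of features (plus \code{label} if \code{labels}
#'   not given).
#' @param labels label vector.
#' @param fit_fun function \code{(data, labels) -> model}; the model must
#'   have a \code{predict(model, data)} method returning classes.
#' @param k number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return List: \code{folds} (per-fold \code{eval_report}),
#'   \code{accuracy_mean/sd}, \code{macro_f1_mean/sd}.
#' @export
kfold_cv <- function(data, labels, fit_fun, k = 10, seed = 1) {
  y <- fatigue_factor(labels)
  n <- length(y)
  if (k > n) stop_fcg("k = %d exceeds n = %d", k, n)
  fold <- integer(n)
  with_seed(seed, {
    if (min(table(y)) < k) {
      warning("a class has fewer members than k; falling back to non-stratified folds")
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (cl in levels(y)) {
        rows <- which(y == cl)
        fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
    }
  })
  reports <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- fit_fun(data[tr, , drop = FALSE], y[tr])
    pred <- predict(model, data[te, , drop = FALSE])
    eval_report(y[te], pred, split = sprintf("fold %d/%d", f, k))
  })
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(reports, `[[`, numeric(1), "macro_f1")
  list(folds = reports, accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
       macro_f1_mean = mean(f1), macro_f1_sd = stats::sd(f1), fold_id = fold)
}

#' McNemar's paired test for two classifiers
#'
#' Counts the discordant pairs over a shared test set: \code{b} = model A
#' correct and B wrong, \code{c} = A wrong and B correct. When
#' \code{b + c < 25} an exact two-sided binomial test is used,
#' \code{p = min(1, 2 P(X <= min(b, c)))} with \code{X ~ Bin(b + c, 1/2)};
#' otherwise the continuity-corrected chi-square
#' \code{(|b - c| - 1)^2 / (b + c)} on 1 df.
#'
#' @param preds_a,preds_b predicted classes from the two models.
#' @param labels true classes.
#' @param exact_below use the exact branch when \code{b + c} is below this.
#' @return List of class \code{mcnemar_result}: \code{b}, \code{c},
#'   \code{statistic} (NA in the exact branch), \code{p_value},
#'   \code{method}, and the two accuracies with their gap in percentage
#'   points (\code{delta_pp}).
#' @export
mcnemar_test <- function(preds_a, preds_b, labels, exact_below = 25) {
  if (length(preds_a) != length(labels) || length(preds_b) != length(labels)) {
    stop_fcg("prediction/label lengths differ")
  }
  ok_a <- as.character(preds_a) == as.character(labels)
  ok_b <- as.character(preds_b) == as.character(labels)
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    p <- 1; stat <- NA_real_; method <- "exact binomial"
  } else if (b + cc < exact_below) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    stat <- NA_real_; method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  acc_a <- mean(ok_a); acc_b <- mean(ok_b)
  structure(list(b = b, c = cc, statistic = stat, p_value = p, method = method,
                 accuracy_a = acc_a, accuracy_b = acc_b,
                 delta_pp = accuracy_gap(100 * acc_a, 100 * acc_b)),
            class = "mcnemar_result")
}

#' Accuracy gap in percentage points
#' @param acc_a,acc_b accuracies on the percent scale.
#' @return \code{acc_a - acc_b}.
#' @export
accuracy_gap <- function(acc_a, acc_b) acc_a - acc_b

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d%s, p = %.4g; acc %.1f%% vs %.1f%% (delta %.1f pp)\n",
              x$method, x$b, x$c,
              if (is.na(x$statistic)) "" else sprintf(", chi2 = %.3f", x$statistic),
              x$p_value, 100 * x$accuracy_a, 100 * x$accuracy_b, x$delta_pp))
  invisible(x)
}

#' Segment-duration sensitivity analysis
#'
#' Re-segments the raw sessions at each duration, keeps the session-to-split
#' assignment fixed (identical train/test split at session granularity for
#' every duration) and evaluates the same model specification each time.
#'
#' @param study a \code{synth_study}.
#' @param durations segment durations in seconds.
#' @param fit_fun function \code{(segments, labels) -> model} with a
#'   \code{predict(model, segments)} method; see \code{\link{hrv_model_spec}}
#'   for a features-based specification.
#' @param test_fraction session-level test share.
#' @param seed split/fit seed.
#' @param ... forwarded to \code{\link{preprocess_study}}.
#' @return data.frame: duration, n segments, accuracy, macro precision,
#'   recall and F1.
#' @export
duration_sensitivity <- function(study, durations = c(10, 15, 20, 30, 60, 90, 120),
                                 fit_fun, test_fraction = 0.2, seed = 1, ...) {
  if (max(durations) > study$session_duration_s) {
    stop_fcg("duration %g s exceeds session length %g s", max(durations),
             study$session_duration_s)
  }
  # fixed session-level assignment shared by all durations
  sess_tab <- study$manifest
  sess_plan <- split_segments(
    data.frame(subject_id = sess_tab$subject_id, day = sess_tab$day,
               session = sess_tab$session, label = sess_tab$label),
    strategy = "segment", test_fraction = test_fraction, seed = seed)[[1]]
  test_keys <- sess_tab$key[sess_plan$test]
  rows <- lapply(durations, function(d) {
    prep <- preprocess_study(study, window_s = d, ...)
    segs <- prep$segments
    keys <- vapply(segs, function(s) sprintf("%s_d%02d_%s", s$subject_id, s$day, s$session), "")
    te <- keys %in% test_keys
    y <- segment_labels(segs)
    model <- with_seed(seed, fit_fun(segs[!te], y[!te]))
    pred <- predict(model, segs[te])
    rep <- eval_report(y[te], pred, split = sprintf("%g s segments", d))
    data.frame(duration_s = d, n_segments = length(segs),
               accuracy = rep$accuracy, macro_precision = rep$macro_precision,
               macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1)
  })
  do.call(rbind, rows)
}

#' HRV-features model specification for evaluation drivers
#'
#' Adapts a feature-table classifier (threshold/rule/weighted/classical) to
#' the segment-list interface used by \code{\link{duration_sensitivity}}:
#' features are extracted from the segments, unusable segments are predicted
#' as the training majority class.
#'
#' @param fit function \code{(features, labels) -> model}.
#' @param min_span_s forwarded to \code{\link{extract_feature_table}}.
#' @return A fit function \code{(segments, labels) -> model} whose model
#'   predicts from segment lists.
#' @export
hrv_model_spec <- function(fit, min_span_s = 5) {
  function(segments, labels) {
    ft <- extract_feature_table(segments, min_span_s = min_span_s)
    ok <- ft$usable
    model <- fit(ft[ok, , drop = FALSE], fatigue_factor(labels)[ok])
    majority <- names(which.max(table(fatigue_factor(labels))))
    structure(list(inner = model, majority = majority, min_span_s = min_span_s),
              class = "hrv_segment_clf")
  }
}

#' @export
predict.hrv_segment_clf <- function(object, newdata, ...) {
  ft <- extract_feature_table(newdata, min_span_s = object$min_span_s)
  out <- rep(object$majority, nrow(ft))
  ok <- ft$usable
  if (any(ok)) out[ok] <- as.character(predict(object$inner, ft[ok, , drop = FALSE]))
  fatigue_factor(out)
}

#' Ablation comparison of the deep model
#'
#' Trains the full CNN-BiLSTM and its two ablation variants with an
#' identical split, seed and training budget, and reports them side by side.
#'
#' @param x segment matrix or list (see \code{\link{fit_cbl}}).
#' @param y labels.
#' @param split a \code{split_plan} over the rows of \code{x}.
#' @param config base \code{\link{cbl_config}}.
#' @param seed training seed shared by the three variants.
#' @param ... forwarded to \code{\link{fit_cbl}} (e.g. \code{epochs},
#'   \code{lr}).
#' @return List of class \code{ablation_result}: per-variant
#'   \code{eval_report}s and a comparison data.frame.
#' @export
run_ablation <- function(x, y, split, config = cbl_config(), seed = 1, ...) {
  stopifnot(inherits(split, "split_plan"))
  if (is.list(x) && !is.matrix(x)) x <- segments_to_matrix(x, config$input_len)
  y <- fatigue_factor(y)
  variants <- list(full = config,
                   cnn_only = build_variant("cnn_only", config),
                   bilstm_only = build_variant("bilstm_only", config))
  reports <- lapply(names(variants), function(v) {
    m <- fit_cbl(x[split$train, , drop = FALSE], y[split$train],
                 config = variants[[v]], seed = seed, ...)
    pred <- predict(m, x[split$test, , drop = FALSE])
    eval_report(y[split$test], pred,
                split = sprintf("%s | %s", v, split$description))
  })
  names(reports) <- names(variants)
  comparison <- data.frame(
    variant = names(variants),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    macro_f1 = vapply(reports, `[[`, numeric(1), "macro_f1"),
    row.names = NULL)
  structure(list(reports = reports, comparison = comparison,
                 test = split$test),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
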