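# Interpretable baselines and classical ML classifiers on HRV features.
# Every fit function returns a classed S3 object whose predict() is a pure
# function of (model, features); all grid searches use deterministic
# tie-breaking so refits on identical data give identical models.

# candidate cutpoints: midpoints of sorted unique values
cut_candidates <- function(x, max_n = 200) {
  u <- sort(unique(x))
  if (length(u) < 2) return(numeric(0))
  mid <- (u[-1] + u[-length(u)]) / 2
  if (length(mid) > max_n) {
    mid <- mid[unique(round(seq(1, length(mid), length.out = max_n)))]
  }
  mid
}

# best (c1 <= c2) pair for an ordered 3-class 1-D rule, exact search via
# cumulative class counts; ties -> smaller c1, then smaller c2
best_two_cutoffs <- function(x, y, cands) {
  lev <- fatigue_levels()
  n1 <- cumsum_counts(x, y == lev[1], cands)
  n2 <- cumsum_counts(x, y == lev[2], cands)
  n3 <- cumsum_counts(x, y == lev[3], cands)
  total3 <- sum(y == lev[3])
  m <- length(cands)
  # correct(c1, c2) = n1[c1] + (n2[c2] - n2[c1]) + (total3 - n3[c2])
  a <- n1 - n2              # choose c1 <= c2 maximizing a[c1]
  b <- n2 - n3              # plus b[c2] + total3
  best_a <- cummax_first(a)
  score <- b + best_a$value
  j <- which.max(score)     # which.max returns the first maximum: smaller c2
  i <- best_a$index[j]
  list(c1 = cands[i], c2 = cands[j],
       correct = score[j] + total3)
}

cumsum_counts <- function(x, mask, cands) {
  vapply(cands, function(cv) sum(mask & x <= cv), numeric(1))
}

# running max keeping the first (smallest-index) argmax
cummax_first <- function(a) {
  v <- a; idx <- seq_along(a)
  for (i in seq_along(a)[-1]) {
    if (a[i] <= v[i - 1]) { v[i] <- v[i - 1]; idx[i] <- idx[i - 1] }
  }
  list(value = v, index = idx)
}

#' Fit a single-feature threshold classifier
#'
#' Exhaustive search over candidate cutoff pairs (midpoints of sorted unique
#' training values) and both orientations, maximizing training accuracy.
#' Ties break deterministically towards the smaller first cutoff, then the
#' smaller second cutoff, then the positive direction (larger value = more
#' fatigued).
#'
#' @param features data.frame containing the feature column.
#' @param labels fatigue labels.
#' @param feature_name feature to threshold (e.g. \code{"RMSSD"}).
#' @return Object of class \code{threshold_clf}.
#' @export
fit_threshold_classifier <- function(features, labels, feature_name) {
  x <- feature_vector(features, feature_name)
  y <- fatigue_factor(labels)
  stopifnot(length(x) == length(y))
  if (any(table(y) == 0)) stop_fcg("need >= 1 training example per class")
  cands <- cut_candidates(x)
  if (!length(cands)) {
    warning(sprintf("constant feature %s; degenerate majority-class model", feature_name))
    maj <- fatigue_levels()[which.max(table(y))]
    return(structure(list(feature = feature_name, direction = 1L,
                          c1 = Inf, c2 = Inf, majority = maj,
                          train_accuracy = max(table(y)) / length(y)),
                     class = "threshold_clf"))
  }
  up <- best_two_cutoffs(x, y, cands)        # larger value = more fatigued
  dn <- best_two_cutoffs(-x, y, -rev(cands)) # opposite orientation
  if (up$correct >= dn$correct) {
    model <- list(feature = feature_name, direction = 1L, c1 = up$c1, c2 = up$c2,
                  train_accuracy = up$correct / length(y))
  } else {
    model <- list(feature = feature_name, direction = -1L, c1 = dn$c1, c2 = dn$c2,
                  train_accuracy = dn$correct / length(y))
  }
  structure(model, class = "threshold_clf")
}

feature_vector <- function(features, name) {
  if (is.null(features[[name]])) stop_fcg("feature `%s` missing", name)
  v <- features[[name]]
  if (anyNA(v)) stop_fcg("feature `%s` contains NA (unusable segments must be dropped first)", name)
  as.numeric(v)
}

#' @export
predict.threshold_clf <- function(object, newdata, ...) {
  x <- feature_vector(newdata, object$feature) * object$direction
  if (!is.null(object$majority)) {
    return(fatigue_factor(rep(object$majority, length(x))))
  }
  lev <- fatigue_levels()
  # direction +1: low scores = least fatigued (normal); c1/c2 are on the
  # oriented axis
  cls <- ifelse(x <= object$c1, lev[1], ifelse(x <= object$c2, lev[2], lev[3]))
  fatigue_factor(cls)
}

#' @export
print.threshold_clf <- function(x, ...) {
  if (!is.null(x$majority)) {
    cat(sprintf("<threshold_clf> degenerate: always `%s`\n", x$majority))
  } else {
    dir <- if (x$direction > 0) "" else " (reversed)"
    cat(sprintf("<threshold_clf> %s%s: normal <= %.4g < slight <= %.4g < fatigued (train acc %.3f)\n",
                x$feature, dir, x$c1, x$c2, x$train_accuracy))
  }
  invisible(x)
}

#' Fit the hand-crafted two-feature decision rule
#'
#' Fixed rule template over MeanRR and RMSSD: \emph{fatigued} if
#' \code{MeanRR < a} and \code{RMSSD < b}; \emph{normal} if
#' \code{MeanRR >= c} and \code{RMSSD >= d}; otherwise \emph{slight} —
#' with \code{a <= c}, \code{b <= d} fitted by exhaustive grid search
#' maximizing training accuracy (deterministic tie-breaks towards smaller
#' cutoffs).
#'
#' @param features data.frame with \code{MeanRR} and \code{RMSSD} columns.
#' @param labels fatigue labels.
#' @param grid_n maximum number of candidate levels per feature.
#' @return Object of class \code{rule_clf}.
#' @export
fit_rule_based <- function(features, labels, grid_n = 40) {
  rrv <- feature_vector(features, "MeanRR")
  rms <- feature_vector(features, "RMSSD")
  y <- fatigue_factor(labels)
  ca <- c(-Inf, cut_candidates(rrv, grid_n), Inf)
  cb <- c(-Inf, cut_candidates(rms, grid_n), Inf)
  lev <- fatigue_levels()
  # F_k(a, b) = # class k with MeanRR < a & RMSSD < b (2-D cumulative);
  # G_k(c, d) = # class k with MeanRR >= c & RMSSD >= d. With a <= c and
  # b <= d the two rule regions are disjoint, so
  # correct = F_fat - F_sli (at a,b) + G_nor - G_sli (at c,d) + n_sli:
  # maximize term1 and, over the admissible corner, term2 via a suffix max.
  count2d <- function(mask, op) {
    outer(seq_along(ca), seq_along(cb), Vectorize(function(i, j) {
      if (op == "lt") sum(mask & rrv < ca[i] & rms < cb[j])
      else sum(mask & rrv >= ca[i] & rms >= cb[j])
    }))
  }
  Fd <- count2d(y == lev[3], "lt") - count2d(y == lev[2], "lt")
  Gd <- count2d(y == lev[1], "ge") - count2d(y == lev[2], "ge")
  # suffix max of Gd over (c >= a, d >= b), tracking first (smallest) argmax
  ni <- nrow(Gd); nj <- ncol(Gd)
  best <- Gd; bi <- matrix(rep(seq_len(ni), nj), ni); bj <- matrix(rep(seq_len(nj), each = ni), ni)
  for (i in ni:1) for (j in nj:1) {
    if (i < ni && best[i + 1, j] > best[i, j]) {
      best[i, j] <- best[i + 1, j]; bi[i, j] <- bi[i + 1, j]; bj[i, j] <- bj[i + 1, j]
    }
    if (j < nj && best[i, j + 1] > best[i, j]) {
      best[i, j] <- best[i, j + 1]; bi[i, j] <- bi[i, j + 1]; bj[i, j] <- bj[i, j + 1]
    }
  }
  score <- Fd + best
  k <- which.max(score)  # column-major first max: smallest a then b
  i <- (k - 1) %% ni + 1; j <- (k - 1) %/% ni + 1
  model <- list(a = ca[i], b = cb[j], c = ca[bi[i, j]], d = cb[bj[i, j]],
                train_accuracy = (score[k] + sum(y == lev[2])) / length(y))
  structure(model, class = "rule_clf")
}

#' @export
predict.rule_clf <- function(object, newdata, ...) {
  rrv <- feature_vector(newdata, "MeanRR")
  rms <- feature_vector(newdata, "RMSSD")
  lev <- fatigue_levels()
  cls <- ifelse(rrv < object$a & rms < object$b, lev[3],
                ifelse(rrv >= object$c & rms >= object$d, lev[1], lev[2]))
  fatigue_factor(cls)
}

#' @export
print.rule_clf <- function(x, ...) {
  cat(sprintf("IF MeanRR < %.4g ms AND RMSSD < %.4g ms THEN fatigued\n", x$a, x$b))
  cat(sprintf("ELSE IF MeanRR >= %.4g ms AND RMSSD >= %.4g ms THEN normal ELSE slight\n",
              x$c, x$d))
  invisible(x)
}

#' Fit the equal-weight three-feature scoring baseline
#'
#' Standardizes the three features with training statistics, aligns their
#' signs with fatigue (+MeanHR, -RMSSD, +LF/HF by default), averages them
#' with equal weights into a fatigue score, and fits two score cutoffs by
#' the exact two-cutoff search. Prediction is monotone in the score.
#'
#' @param features data.frame of HRV features.
#' @param labels fatigue labels.
#' @param feature_names the three features to combine.
#' @param signs alignment of each feature with fatigue (+1 or -1).
#' @return Object of class \code{weighted_clf}.
#' @export
fit_weighted_score <- function(features, labels,
                               feature_names = c("MeanHR", "RMSSD", "LF_HF"),
                               signs = c(1, -1, 1)) {
  stopifnot(length(feature_names) == 3, length(signs) == 3)
  y <- fatigue_factor(labels)
  mu <- sdv <- numeric(3)
  cols <- lapply(seq_len(3), function(k) feature_vector(features, feature_names[k]))
  for (k in 1:3) {
    mu[k] <- mean(cols[[k]]); sdv[k] <- stats::sd(cols[[k]])
    if (sdv[k] == 0) {
      warning(sprintf("zero-variance feature %s; its z-score is 0", feature_names[k]))
    }
  }
  model <- list(feature_names = feature_names, signs = signs, mu = mu, sd = sdv,
                weights = rep(1 / 3, 3))
  score <- weighted_score(model, features)
  cands <- cut_candidates(score)
  cuts <- best_two_cutoffs(score, y, cands)
  model$c1 <- cuts$c1; model$c2 <- cuts$c2
  model$train_accuracy <- cuts$correct / length(y)
  structure(model, class = "weighted_clf")
}

weighted_score <- function(model, features) {
  z <- vapply(seq_len(3), function(k) {
    v <- feature_vector(features, model$feature_names[k])
    if (model$sd[k] > 0) model$signs[k] * (v - model$mu[k]) / model$sd[k] else rep(0, length(v))
  }, numeric(nrow(features)))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  as.numeric(z %*% model$weights)
}

#' @export
predict.weighted_clf <- function(object, newdata, ...) {
  s <- weighted_score(object, newdata)
  lev <- fatigue_levels()
  fatigue_factor(ifelse(s <= object$c1, lev[1],
                        ifelse(s <= object$c2, lev[2], lev[3])))
}

#' @export
print.weighted_clf <- function(x, ...) {
  cat(sprintf("<weighted_clf> score = mean(%s) with signs (%s); cutoffs (%.3f, %.3f), train acc %.3f\n",
              paste(x$feature_names, collapse = ", "),
              paste(sprintf("%+d", x$signs), collapse = ", "),
              x$c1, x$c2, x$train_accuracy))
  invisible(x)
}

#' Fit a classical machine-learning classifier on HRV features
#'
#' Wraps the standard implementations: multinomial logistic regression
#' (\code{nnet::multinom}), RBF-kernel SVM (\code{e1071::svm}, one-vs-rest
#' with decision values) and random forest
#' (\code{randomForest::randomForest}, 500 trees). Features are standardized
#' with training statistics for logreg/svm; the stored model carries the full
#' preprocessing so prediction is self-contained.
#'
#' @param kind \code{"logreg"}, \code{"svm_rbf"} or \code{"rf"}.
#' @param features data.frame of HRV features (the 11 canonical columns, or
#'   any numeric subset via \code{feature_names}).
#' @param labels fatigue labels.
#' @param seed RNG seed (random forest).
#' @param feature_names feature columns to use.
#' @return Object of class \code{classical_clf}.
#' @export
fit_classical <- function(kind = c("logreg", "svm_rbf", "rf"), features, labels,
                          seed = 1, feature_names = hrv_feature_names()) {
  kind <- match.arg(kind)
  y <- fatigue_factor(labels)
  if (nlevels(droplevels(y)) < 2) stop_fcg("training labels contain a single class")
  Xdf <- features[, feature_names, drop = FALSE]
  if (anyNA(Xdf)) stop_fcg("feature table contains NA; drop unusable segments first")
  X <- as.matrix(Xdf)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  fit <- with_seed(seed, switch(kind,
    logreg = {
      df <- data.frame(y = y, Xs)
      nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
    },
    svm_rbf = {
      # one-vs-rest: one binary RBF machine per class, argmax decision value.
      # libsvm's decision-value sign depends on training-row order, so each
      # machine is oriented on its own training data.
      lapply(fatigue_levels(), function(cl) {
        yb <- factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest"))
        m <- e1071::svm(Xs, yb, kernel = "radial", scale = FALSE)
        dv <- as.numeric(attr(stats::predict(m, Xs, decision.values = TRUE),
                              "decision.values"))
        flip <- mean(dv[yb == cl]) < mean(dv[yb != cl])
        list(svm = m, sign = if (flip) -1 else 1)
      })
    },
    rf = randomForest::randomForest(X, y, ntree = 500)
  ))
  structure(list(kind = kind, fit = fit, mu = mu, sd = sdv,
                 feature_names = feature_names, classes = fatigue_levels()),
            class = "classical_clf")
}

#' @export
predict.classical_clf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- scale(X, center = object$mu, scale = object$sd)
  out <- switch(object$kind,
    logreg = {
      df <- as.data.frame(Xs)
      as.character(stats::predict(object$fit, newdata = df))
    },
    svm_rbf = {
      dec <- vapply(object$fit, function(m) {
        m$sign * as.numeric(attr(stats::predict(m$svm, Xs, decision.values = TRUE),
                                 "decision.values"))
      }, numeric(nrow(Xs)))
      if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
      object$classes[apply(dec, 1, which.max)]
    },
    rf = as.character(stats::predict(object$fit, X))
  )
  fatigue_factor(out)
}

#' @export
print.classical_clf <- function(x, ...) {
  cat(sprintf("<classical_clf> %s on %d features\n", x$kind,
              length(x$feature_names)))
  invisible(x)
}
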