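#' Names of the 11 HRV features
#'
#' Time domain: MeanRR, SDNN, RMSSD, pNN50, MeanHR. Frequency domain
#' (Welch PSD of the resampled tachogram): LF, HF, LF_HF, HFnorm.
#' Nonlinear (Poincare): SD1, SD2.
#'
#' @return Character vector of length 11.
#' @export
hrv_feature_names <- function() {
  c("MeanRR", "SDNN", "RMSSD", "pNN50", "MeanHR",
    "LF", "HF", "LF_HF", "HFnorm", "SD1", "SD2")
}

#' Pan-Tompkins R-peak detection
#'
#' The classical QRS detector: 5-15 Hz band-pass, 5-point derivative,
#' pointwise squaring, 150-ms moving-window integration, then adaptive dual
#' thresholding of integration-wave peaks with running signal/noise level
#' estimates, a 200-ms refractory period and a search-back pass triggered at
#' 1.66 times the running RR average. Each accepted peak is refined to the
#' argmax of the band-passed signal within +/- 50 ms. Filtering is
#' zero-phase so detected times align with the underlying R waves.
#'
#' @param samples numeric ECG signal (mV).
#' @param fs sampling rate in Hz (>= 100).
#' @param refractory_s refractory period (default 0.2 s).
#' @param searchback_factor missed-beat trigger as a multiple of the running
#'   RR average (default 1.66).
#' @param integration_window_s moving-window integration length (default
#'   0.150 s).
#' @return Object of class \code{rpeak_series}: \code{indices} (1-based
#'   sample indices), \code{times_s}, \code{fs}, and \code{stages} (the
#'   band-passed, derivative, squared and integrated intermediate signals).
#' @export
pan_tompkins <- function(samples, fs, refractory_s = 0.2,
                         searchback_factor = 1.66,
                         integration_window_s = 0.150) {
  check_number(fs, "fs", 100)
  if (length(samples) < 2 * fs) stop_fcg("need >= 2 s of signal, got %.2f s",
                                         length(samples) / fs)
  if (stats::sd(samples) == 0) {
    warning("flat (zero-variance) input; no peaks detected")
    return(new_rpeak_series(integer(0), fs, NULL))
  }
  bp <- bandpass_filter(samples, fs, 5, 15, order = 4)
  dcoef <- c(2, 1, 0, -1, -2) / 8
  dv <- as.numeric(stats::filter(bp, dcoef, method = "convolution", sides = 1))
  dv[is.na(dv)] <- 0
  sq <- dv^2
  mwi <- moving_average_filter(sq, max(3L, round(integration_window_s * fs)))

  refr <- round(refractory_s * fs)
  # candidate fiducial marks: local maxima of the integration wave
  n <- length(mwi)
  is_max <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] &
                     mwi[2:(n - 1)] > mwi[3:n], FALSE)
  cand <- which(is_max)
  if (length(cand) > 1) {
    # merge ringing side lobes: among maxima closer than the refractory
    # period keep the larger one
    keep <- cand[1]
    for (ci in cand[-1]) {
      if (ci - keep[length(keep)] <= refr) {
        if (mwi[ci] > mwi[keep[length(keep)]]) keep[length(keep)] <- ci
      } else keep <- c(keep, ci)
    }
    cand <- keep
  }
  if (!length(cand)) {
    warning("no candidate peaks in integration wave")
    return(new_rpeak_series(integer(0), fs, list(bandpassed = bp, derivative = dv,
                                                 squared = sq, integrated = mwi)))
  }
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_buf <- numeric(0)
  last_skipped <- integer(0)
  for (ci in cand) {
    pk <- mwi[ci]
    if (length(peaks) && (ci - peaks[length(peaks)]) <= refr) next
    if (pk > thr1()) {
      peaks <- c(peaks, ci)
      spki <- 0.125 * pk + 0.875 * spki
      if (length(peaks) > 1) {
        rr_buf <- c(rr_buf, (peaks[length(peaks)] - peaks[length(peaks) - 1]) / fs)
        if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
      }
      last_skipped <- integer(0)
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      last_skipped <- c(last_skipped, ci)
      # search-back: missed-beat window at 1.66x the running RR average
      if (length(peaks) && length(rr_buf)) {
        gap <- (ci - peaks[length(peaks)]) / fs
        if (gap > searchback_factor * mean(rr_buf)) {
          ok <- last_skipped[mwi[last_skipped] > 0.5 * thr1() &
                             (last_skipped - peaks[length(peaks)]) > refr]
          if (length(ok)) {
            sb <- ok[which.max(mwi[ok])]
            ins <- sort(c(peaks[length(peaks)], sb))
            peaks <- c(peaks[-length(peaks)], ins)
            spki <- 0.25 * mwi[sb] + 0.75 * spki
            rr_buf <- c(rr_buf, (ins[2] - ins[1]) / fs)
            if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
            last_skipped <- last_skipped[last_skipped > sb]
          }
        }
      }
    }
  }
  # refine to the argmax of the filtered input within +/- 50 ms (the input is
  # already denoised in the pipeline, so R morphology is intact there),
  # then re-enforce the refractory period
  half <- round(0.05 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(samples[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) > refr)
    refined <- refined[keep]
  }
  new_rpeak_series(refined, fs, list(bandpassed = bp, derivative = dv,
                                     squared = sq, integrated = mwi))
}

new_rpeak_series <- function(indices, fs, stages) {
  structure(list(indices = as.integer(indices),
                 times_s = (as.integer(indices) - 1) / fs,
                 fs = fs, stages = stages),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks @ %g Hz", length(x$indices), x$fs))
  if (length(x$indices) > 1) {
    cat(sprintf(", mean HR %.1f bpm", 60 / mean(diff(x$times_s))))
  }
  cat("\n")
  invisible(x)
}

#' RR intervals from detected R peaks
#'
#' Successive differences in ms, with physiologic gating: intervals outside
#' \code{[300, 2000]} ms are removed and counted.
#'
#' @param peaks an \code{rpeak_series} (or numeric vector of peak times in
#'   seconds).
#' @return An \code{rr_series} (fields \code{rr_ms}, \code{times_s}) with
#'   attribute \code{n_gated}, the number of removed intervals.
#' @export
rr_from_peaks <- function(peaks) {
  times <- if (inherits(peaks, "rpeak_series")) peaks$times_s else as.numeric(peaks)
  if (length(times) < 2) stop_fcg("insufficient beats: need >= 2 peaks, got %d",
                                  length(times))
  rr <- diff(times) * 1000
  ok <- rr >= 300 & rr <= 2000
  out <- structure(list(rr_ms = rr[ok], times_s = times[c(TRUE, ok)]),
                   class = "rr_series")
  attr(out, "n_gated") <- sum(!ok)
  out
}

rr_values <- function(rr) {
  if (inherits(rr, "rr_series")) rr$rr_ms else as.numeric(rr)
}

# population standard deviation (stated so oracles are unambiguous)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Time-domain HRV features
#'
#' MeanRR (ms), SDNN (population SD, ms), RMSSD (ms), pNN50 (% of successive
#' differences exceeding 50 ms in magnitude) and MeanHR
#' (\code{60000 / MeanRR}, bpm).
#'
#' @param rr an \code{rr_series} or numeric RR vector (ms); >= 2 intervals.
#' @return Named numeric vector of the five features.
#' @export
time_domain_features <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 2) stop_fcg("need >= 2 RR intervals, got %d", length(x))
  d <- diff(x)
  c(MeanRR = mean(x), SDNN = sd_pop(x), RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * mean(abs(d) > 50), MeanHR = 60000 / mean(x))
}

# Welch PSD with Hann taper and 50% overlap; one-sided, density scaled so
# sum(psd) * df ~= variance of x.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  norm <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / norm
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = seq(0, by = fs / seg_len, length.out = nf),
       psd = acc / length(starts), df = fs / seg_len)
}

#' Frequency-domain HRV features
#'
#' The RR tachogram is cubic-spline interpolated to a uniform grid
#' (\code{resample_hz}), mean-removed, and analysed with a Welch periodogram
#' (Hann taper, 50\% overlap, segment length \code{min(series, 64 s)}).
#' LF and HF are band power integrals in ms^2 over 0.04-0.15 Hz and
#' 0.15-0.4 Hz; \code{LF_HF = LF/HF}; \code{HFnorm = 100 HF / (LF + HF)}.
#'
#' @param rr an \code{rr_series}; its time span must be at least
#'   \code{min_span_s} (a caveat is logged below 60 s, where ultra-short-term
#'   frequency estimates are statistically weak).
#' @param resample_hz tachogram resampling rate (default 4 Hz).
#' @param lf_band,hf_band band limits in Hz.
#' @param min_span_s minimum admissible tachogram span (default 20 s).
#' @return Named numeric vector: LF, HF, LF_HF, HFnorm.
#' @export
frequency_domain_features <- function(rr, resample_hz = 4,
                                      lf_band = c(0.04, 0.15),
                                      hf_band = c(0.15, 0.4),
                                      min_span_s = 20) {
  if (!inherits(rr, "rr_series")) {
    x <- as.numeric(rr)
    rr <- structure(list(rr_ms = x, times_s = c(0, cumsum(x)) / 1000),
                    class = "rr_series")
  }
  tt <- rr$times_s[-1]
  x <- rr$rr_ms
  if (length(x) < 4) stop_fcg("need >= 4 RR intervals for spectral analysis")
  span <- tt[length(tt)] - tt[1]
  if (span < min_span_s) stop_fcg("tachogram span %.1f s below minimum %g s",
                                  span, min_span_s)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  xi <- stats::spline(tt, x, xout = grid, method = "natural")$y
  xi <- xi - mean(xi)
  ps <- welch_psd(xi, resample_hz, seg_len = min(length(xi), 64 * resample_hz))
  band_power <- function(band) {
    sel <- ps$freq > band[1] & ps$freq <= band[2]
    sum(ps$psd[sel]) * ps$df
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  if (hf == 0) {
    warning("HF power is zero; LF/HF reported as Inf")
    ratio <- Inf
  } else ratio <- lf / hf
  c(LF = lf, HF = hf, LF_HF = ratio,
    HFnorm = if (lf + hf > 0) 100 * hf / (lf + hf) else 0)
}

#' Poincare (nonlinear) HRV features
#'
#' \code{SD1 = sd(diff(RR)) / sqrt(2)} (short-term axis) and
#' \code{SD2 = sqrt(max(0, 2 SDNN^2 - SD1^2))} (long-term axis), population
#' denominators throughout, so \code{SD1^2 + SD2^2 = 2 SDNN^2}.
#'
#' @param rr an \code{rr_series} or numeric RR vector (ms); >= 3 intervals.
#' @return Named numeric vector: SD1, SD2.
#' @export
poincare_features <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 3) stop_fcg("need >= 3 RR intervals, got %d", length(x))
  sd1 <- sd_pop(diff(x)) / sqrt(2)
  sdnn <- sd_pop(x)
  c(SD1 = sd1, SD2 = sqrt(max(0, 2 * sdnn^2 - sd1^2)))
}

#' Extract the 11 HRV features from one segment
#'
#' Runs Pan-Tompkins detection, RR gating and the three feature families.
#' Segments with fewer than 4 detected beats (or too few gated intervals)
#' are flagged unusable: the returned vector is NA-filled with attribute
#' \code{usable = FALSE}, never silently zero-filled.
#'
#' @param segment an \code{ecg_segment} (already denoised).
#' @param min_span_s minimum tachogram span for frequency features.
#' @return Named numeric vector of the 11 features (see
#'   \code{\link{hrv_feature_names}}) with attributes \code{usable} and
#'   \code{provenance}.
#' @export
extract_features <- function(segment, min_span_s = 20) {
  stopifnot(inherits(segment, "ecg_segment"))
  prov <- segment[c("subject_id", "day", "session", "segment_index")]
  unusable <- function(why) {
    warning(sprintf("segment %s/d%d/%s#%d unusable: %s", prov$subject_id,
                    prov$day, prov$session, prov$segment_index, why))
    out <- stats::setNames(rep(NA_real_, 11L), hrv_feature_names())
    structure(out, usable = FALSE, provenance = prov, class = "hrv_features")
  }
  peaks <- tryCatch(suppressWarnings(pan_tompkins(segment$samples, segment$fs)),
                    error = function(e) NULL)
  if (is.null(peaks) || length(peaks$indices) < 4) {
    return(unusable("fewer than 4 detected beats"))
  }
  rr <- rr_from_peaks(peaks)
  if (length(rr$rr_ms) < 4) return(unusable("fewer than 4 gated RR intervals"))
  td <- time_domain_features(rr)
  fd <- tryCatch(suppressWarnings(
    frequency_domain_features(rr, min_span_s = min_span_s)),
    error = function(e) NULL)
  if (is.null(fd)) return(unusable("tachogram span too short for spectral features"))
  pc <- poincare_features(rr)
  out <- c(td, fd, pc)[hrv_feature_names()]
  structure(out, usable = TRUE, provenance = prov, class = "hrv_features")
}

#' Feature table for a list of segments
#'
#' @param segments list of \code{ecg_segment}.
#' @param min_span_s forwarded to \code{\link{extract_features}}.
#' @return data.frame: provenance columns, \code{label}, the 11 features and
#'   \code{usable}. Unusable segments carry NA features.
#' @export
extract_feature_table <- function(segments, min_span_s = 20) {
  rows <- lapply(segments, function(s) {
    f <- suppressWarnings(extract_features(s, min_span_s = min_span_s))
    prov <- attr(f, "provenance")
    cbind(data.frame(subject_id = prov$subject_id, day = prov$day,
                     session = prov$session, segment_index = prov$segment_index,
                     label = as.character(s$label), stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(f))),
          data.frame(usable = isTRUE(attr(f, "usable"))))
  })
  out <- do.call(rbind, rows)
  out$label <- fatigue_factor(out$label)
  out
}

#' Beat-detection F1 against ground truth
#'
#' Greedy one-to-one matching of detected to true R times within a
#' tolerance; returns precision, recall and F1.
#'
#' @param detected_s,truth_s numeric vectors of peak times (s).
#' @param tol_s matching tolerance (default 0.05 s).
#' @return Named vector: precision, recall, f1, tp, fp, fn.
#' @export
detection_f1 <- function(detected_s, truth_s, tol_s = 0.05) {
  if (!length(truth_s)) stop_fcg("empty ground truth")
  used <- logical(length(truth_s))
  tp <- 0L
  for (d in detected_s) {
    j <- which(!used & abs(truth_s - d) <= tol_s)
    if (length(j)) {
      used[j[which.min(abs(truth_s[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected_s) - tp
  fn <- length(truth_s) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}
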