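#' Centered moving-average filter
#'
#' The N-point sliding average used to suppress powerline interference.
#' Edges use the shrink-to-valid window so length is preserved. The gain at
#' frequency f follows the Dirichlet kernel
#' \code{|sin(pi f N / fs) / (N sin(pi f / fs))|}; note that at fs = 200 Hz
#' the default N = 5 attenuates 50 Hz to gain 0.2 rather than nulling it
#' (N = 4 gives an exact null).
#'
#' @param samples numeric signal.
#' @param n window length in samples (>= 1, <= length of signal).
#' @return Filtered signal, same length.
#' @export
moving_average_filter <- function(samples, n = 5) {
  len <- length(samples)
  if (n < 1 || n != round(n)) stop_fcg("`n` must be a positive integer")
  if (n > len) stop_fcg("window n = %d longer than signal (%d samples)", n, len)
  if (n == 1) return(samples)
  half_lo <- floor((n - 1) / 2)
  half_hi <- n - 1 - half_lo
  cs <- cumsum(c(0, samples))
  i <- seq_len(len)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove baseline wander
#'
#' Default: zero-phase (forward-backward) Butterworth high-pass, order 4 at
#' 0.5 Hz, which attenuates 0.3 Hz drift by more than 20 dB while changing
#' pass-band (>= 1 Hz) amplitudes by under 1 dB and preserving R-peak times.
#' Alternative \code{method = "median"} subtracts a running-median baseline
#' estimate (window \code{median_window_s}).
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param method \code{"highpass"} or \code{"median"}.
#' @param cutoff_hz high-pass corner frequency.
#' @param order Butterworth order (before the forward-backward doubling).
#' @param median_window_s running-median window for \code{method = "median"}.
#' @return Baseline-corrected signal, same length.
#' @export
remove_baseline <- function(samples, fs, method = c("highpass", "median"),
                            cutoff_hz = 0.5, order = 4, median_window_s = 0.6) {
  method <- match.arg(method)
  if (!length(samples)) return(samples)
  if (method == "highpass") {
    filt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
    check_filter_stable(filt, order)
    zero_phase_filter(filt, samples)
  } else {
    k <- round(median_window_s * fs)
    if (k %% 2 == 0) k <- k + 1
    k <- max(3L, min(k, length(samples) - (1 - length(samples) %% 2)))
    samples - stats::runmed(samples, k, endrule = "constant")
  }
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero net phase shift,
#' so R-peak timing is preserved). The default 0.5-40 Hz band retains ECG
#' components while rejecting drift and muscle noise.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param lo_hz,hi_hz band edges, \code{0 < lo_hz < hi_hz < fs/2}.
#' @param order total filter order (even; default 4).
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(samples, fs, lo_hz = 0.5, hi_hz = 40, order = 4) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2)) {
    stop_fcg("band edges must satisfy 0 < lo < hi < fs/2; got (%g, %g) at fs %g",
             lo_hz, hi_hz, fs)
  }
  if (order %% 2 != 0 || order < 2) stop_fcg("`order` must be an even integer >= 2")
  if (!length(samples)) return(samples)
  filt <- signal::butter(order / 2, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  check_filter_stable(filt, order)
  zero_phase_filter(filt, samples)
}

check_filter_stable <- function(filt, order) {
  p <- polyroot(rev(filt$a))
  if (any(Mod(p) >= 1 - 1e-10)) {
    stop_fcg(paste0("unstable filter design at order %d (corner too close to 0 ",
                    "relative to fs); reduce the order"), order)
  }
  invisible(TRUE)
}

# signal::filtfilt with reflective padding to tame edge transients.
zero_phase_filter <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, max(3 * (length(filt$a) + length(filt$b)), 200))
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- signal::filtfilt(filt, xp)
    y[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Residual-based signal-to-noise ratio
#'
#' \code{SNR = 10 log10(power(cleaned) / power(raw - cleaned))} in dB, i.e.
#' the cleaned signal is taken as the signal estimate and what filtering
#' removed as the noise estimate. Power is the mean-removed (AC) power of
#' each component: a beat train has a nonzero mean, and the static electrode
#' offset that baseline removal strips must not be counted as noise.
#' Capped at +/- 99 dB.
#'
#' @param raw,cleaned equal-length numeric signals.
#' @return SNR in dB.
#' @export
estimate_snr <- function(raw, cleaned) {
  if (!length(raw)) stop_fcg("zero-length segment")
  if (length(raw) != length(cleaned)) stop_fcg("`raw` and `cleaned` lengths differ")
  res <- raw - cleaned
  p_sig <- mean((cleaned - mean(cleaned))^2)
  p_res <- mean((res - mean(res))^2)
  if (p_res < 1e-12) return(if (p_sig < 1e-12) -99 else 99)
  if (p_sig < 1e-12) return(-99)
  max(-99, min(99, 10 * log10(p_sig / p_res)))
}

#' Artifact-based segment rejection rule
#'
#' A segment is rejected iff any raw sample exceeds the amplitude bound
#' (checked first) or the residual SNR falls below the floor.
#'
#' @param raw,cleaned the raw and denoised segment signals.
#' @param amp_mv amplitude bound in mV (default 5).
#' @param snr_db SNR floor in dB (default 15).
#' @return List: \code{keep} (logical), \code{reason} (\code{NA},
#'   \code{"amplitude"} or \code{"snr"}), \code{snr_db} (estimated SNR).
#' @export
reject_segment <- function(raw, cleaned, amp_mv = 5, snr_db = 15) {
  snr <- estimate_snr(raw, cleaned)
  if (any(abs(raw) > amp_mv)) {
    list(keep = FALSE, reason = "amplitude", snr_db = snr)
  } else if (snr < snr_db) {
    list(keep = FALSE, reason = "snr", snr_db = snr)
  } else {
    list(keep = TRUE, reason = NA_character_, snr_db = snr)
  }
}

#' Denoise an ECG signal
#'
#' The full conditioning chain: baseline removal, N-point moving average
#' (powerline suppression) and 0.5-40 Hz zero-phase band-pass. Length and
#' sampling rate are never changed.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param baseline_method see \code{\link{remove_baseline}}.
#' @param ma_n moving-average length (samples).
#' @param band band-pass edges \code{c(lo, hi)} in Hz.
#' @param order band-pass order.
#' @return Denoised signal, same length.
#' @export
preprocess_signal <- function(samples, fs, baseline_method = "highpass",
                              ma_n = 5, band = c(0.5, 40), order = 4) {
  x <- remove_baseline(samples, fs, method = baseline_method)
  x <- moving_average_filter(x, ma_n)
  bandpass_filter(x, fs, band[1], band[2], order)
}

#' Cut a record into fixed-duration labelled segments
#'
#' Non-overlapping windows when \code{hop_s = window_s} (default); the
#' trailing partial window is dropped, so a 600-s session at 30-s windows
#' yields exactly 20 segments. Every segment inherits the session label.
#'
#' @param record an \code{ecg_record} (with a Borg score, unless
#'   \code{label} is supplied).
#' @param window_s window length in seconds (> 0).
#' @param hop_s hop between window starts (default \code{window_s}).
#' @param label optional fatigue class overriding the record's Borg-derived
#'   label.
#' @param cutoffs Borg cutoffs for the derived label.
#' @return List of \code{\link{ecg_segment}}; empty (with a warning) if the
#'   record is shorter than one window.
#' @export
segment_record <- function(record, window_s = 30, hop_s = window_s,
                           label = NULL, cutoffs = c(11L, 14L)) {
  stopifnot(inherits(record, "ecg_record"))
  check_number(window_s, "window_s", lower = .Machine$double.eps)
  if (is.null(label)) {
    if (is.null(record$borg_score)) stop_fcg("record has no Borg score and no label given")
    label <- map_borg_to_class(record$borg_score, cutoffs)
  }
  w <- round(window_s * record$fs)
  h <- round(hop_s * record$fs)
  n <- length(record$samples)
  if (n < w) {
    warning(sprintf("record (%.1f s) shorter than one %g-s window; no segments",
                    record$duration_s, window_s))
    return(list())
  }
  starts <- seq(1L, n - w + 1L, by = h)
  lapply(seq_along(starts), function(i) {
    ecg_segment(record$samples[starts[i]:(starts[i] + w - 1L)], record$fs,
                label = label, subject_id = record$subject_id,
                day = record$day, session = record$session,
                segment_index = i - 1L)
  })
}

#' Preprocess and segment a whole study
#'
#' For each session: denoise, segment both raw and cleaned signals, apply the
#' rejection rule per segment, and collect kept segments plus a rejection
#' report.
#'
#' @param study a \code{synth_study} (or compatible list with
#'   \code{records}).
#' @param window_s segment window (s).
#' @param amp_mv,snr_db rejection thresholds (see
#'   \code{\link{reject_segment}}).
#' @param ... filtering options passed to \code{\link{preprocess_signal}}.
#' @return List: \code{segments} (kept, cleaned \code{ecg_segment}s),
#'   \code{report} (per-segment data.frame: provenance, keep, reason,
#'   snr_db), \code{rejection_rate} (fraction rejected).
#' @export
preprocess_study <- function(study, window_s = 30, amp_mv = 5, snr_db = 15,
                             ...) {
  segments <- list()
  rows <- list()
  for (key in names(study$records)) {
    rec <- study$records[[key]]
    cleaned <- preprocess_signal(rec$samples, rec$fs, ...)
    crec <- rec; crec$samples <- cleaned
    raw_segs <- segment_record(rec, window_s)
    cln_segs <- segment_record(crec, window_s)
    for (i in seq_along(raw_segs)) {
      verdict <- reject_segment(raw_segs[[i]]$samples, cln_segs[[i]]$samples,
                                amp_mv = amp_mv, snr_db = snr_db)
      s <- cln_segs[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, subject_id = s$subject_id, day = s$day,
        session = s$session, segment_index = s$segment_index,
        label = as.character(s$label), keep = verdict$keep,
        reason = verdict$reason, snr_db = verdict$snr_db,
        stringsAsFactors = FALSE)
      if (verdict$keep) segments[[length(segments) + 1L]] <- s
    }
  }
  report <- do.call(rbind, rows)
  list(segments = segments, report = report,
       rejection_rate = if (is.null(report)) 0 else mean(!report$keep))
}
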