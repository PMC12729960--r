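#' Class-conditioned RR-synthesis parameters
#'
#' Parameters controlling the synthetic RR-interval process for one fatigue
#' class: mean heart rate, total RR variability (SDNN), the LF/HF band-power
#' ratio of the RR modulation, and a multiplier on the HF (vagally driven,
#' beat-to-beat) component.
#'
#' @param mean_hr_bpm mean heart rate in beats per minute, in \code{[30, 220]}.
#' @param sdnn_target_ms target SDNN of the RR series in ms (>= 0).
#' @param lf_hf_ratio LF/HF band-power ratio of the modulation (> 0).
#' @param rmssd_scale multiplier on the HF component amplitude; values < 1
#'   emulate vagal withdrawal (lower RMSSD/HF) under fatigue.
#' @return Object of class \code{synth_class_params}.
#' @export
synth_class_params <- function(mean_hr_bpm, sdnn_target_ms = 50,
                               lf_hf_ratio = 1, rmssd_scale = 1) {
  check_number(mean_hr_bpm, "mean_hr_bpm", 30, 220)
  check_number(sdnn_target_ms, "sdnn_target_ms", 0)
  check_number(lf_hf_ratio, "lf_hf_ratio", .Machine$double.eps)
  check_number(rmssd_scale, "rmssd_scale", 0)
  structure(list(mean_hr_bpm = mean_hr_bpm, sdnn_target_ms = sdnn_target_ms,
                 lf_hf_ratio = lf_hf_ratio, rmssd_scale = rmssd_scale),
            class = "synth_class_params")
}

#' Default per-class synthesis parameters
#'
#' Fatigue raises mean heart rate and sympathovagal balance (LF/HF) and
#' lowers overall and beat-to-beat variability, the directions reported for
#' physical fatigue; the magnitudes are the package's synthetic-study
#' defaults, not physiological claims.
#'
#' @return Named list of \code{synth_class_params}, one per fatigue class.
#' @export
default_class_params <- function() {
  list(normal   = synth_class_params(65, sdnn_target_ms = 50, lf_hf_ratio = 1.0, rmssd_scale = 1.0),
       slight   = synth_class_params(80, sdnn_target_ms = 40, lf_hf_ratio = 2.0, rmssd_scale = 0.7),
       fatigued = synth_class_params(95, sdnn_target_ms = 30, lf_hf_ratio = 3.5, rmssd_scale = 0.5))
}

#' Wearable-ECG noise parameters
#'
#' The four noise sources of wearable recordings: respiratory baseline wander
#' (slow sinusoid), 50 Hz powerline interference, broadband white noise, and
#' transient motion artifacts (0.5-s raised-cosine bursts at Poisson times).
#'
#' @param baseline_amp_mv,baseline_freq_hz amplitude (mV) and frequency
#'   (< 1 Hz) of the baseline-wander sinusoid.
#' @param powerline_amp_mv amplitude (mV) of the 50 Hz interference.
#' @param white_sd_mv standard deviation (mV) of additive white noise.
#' @param artifact_rate_per_min,artifact_amp_mv Poisson rate and amplitude of
#'   motion-artifact bursts.
#' @return Object of class \code{noise_params}.
#' @export
noise_params <- function(baseline_amp_mv = 0.015, baseline_freq_hz = 0.25,
                         powerline_amp_mv = 0.008, white_sd_mv = 0.004,
                         artifact_rate_per_min = 0.3, artifact_amp_mv = 6) {
  for (nm in c("baseline_amp_mv", "powerline_amp_mv", "white_sd_mv",
               "artifact_rate_per_min", "artifact_amp_mv")) {
    check_number(get(nm), nm, 0)
  }
  check_number(baseline_freq_hz, "baseline_freq_hz", 0, 1 - 1e-9)
  structure(list(baseline_amp_mv = baseline_amp_mv,
                 baseline_freq_hz = baseline_freq_hz,
                 powerline_amp_mv = powerline_amp_mv, white_sd_mv = white_sd_mv,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amp_mv = artifact_amp_mv),
            class = "noise_params")
}

#' Noise-free generation parameters
#' @return A \code{noise_params} with every amplitude zero.
#' @export
zero_noise_params <- function() {
  noise_params(0, 0.25, 0, 0, 0, 0)
}

# Band centres chosen mid-band of the standard LF 0.04-0.15 / HF 0.15-0.4 Hz
# ranges; widths keep ~all band power inside the standard limits.
LF_CENTER_HZ <- 0.095
HF_CENTER_HZ <- 0.275
LF_WIDTH_HZ <- 0.02
HF_WIDTH_HZ <- 0.04

#' Generate a synthetic RR-interval series
#'
#' RR modulation is built by inverse-spectrum synthesis: a Gaussian-band
#' two-component spectrum (LF centred 0.095 Hz, HF centred 0.275 Hz) with
#' band powers in ratio \code{lf_hf_ratio} (HF additionally scaled by
#' \code{rmssd_scale^2}), filled with seeded complex Gaussian noise,
#' inverse-transformed, and rescaled so the RR variance equals
#' \code{sdnn_target_ms^2}. Beats are then placed iteratively:
#' \code{t[k+1] = t[k] + RR(t[k])/1000}.
#'
#' @param params a \code{\link{synth_class_params}}.
#' @param duration_s series duration in seconds (>= 10).
#' @param seed integer seed; identical \code{(params, duration_s, seed)} give
#'   identical output. \code{NULL} uses the current RNG stream.
#' @return Object of class \code{rr_series}: fields \code{rr_ms} (intervals),
#'   \code{times_s} (R-peak times, \code{length(rr_ms) + 1}).
#' @export
generate_rr_series <- function(params, duration_s, seed = NULL) {
  stopifnot(inherits(params, "synth_class_params"))
  check_number(duration_s, "duration_s", 10)
  with_seed(seed, {
    mean_rr <- 60000 / params$mean_hr_bpm
    if (params$sdnn_target_ms == 0) {
      n <- floor((duration_s - 0.3) * 1000 / mean_rr)
      rr <- rep(mean_rr, n)
    } else {
      fs_mod <- 4
      n_grid <- 2^ceiling(log2(duration_s * fs_mod + 1))
      f <- seq(0, fs_mod / 2, length.out = n_grid / 2 + 1)
      shape <- params$lf_hf_ratio *
        exp(-(f - LF_CENTER_HZ)^2 / (2 * LF_WIDTH_HZ^2)) +
        params$rmssd_scale^2 *
        exp(-(f - HF_CENTER_HZ)^2 / (2 * HF_WIDTH_HZ^2))
      amp <- sqrt(shape)
      re <- stats::rnorm(length(f)); im <- stats::rnorm(length(f))
      half <- complex(real = amp * re, imaginary = amp * im)
      half[1] <- 0
      half[length(half)] <- complex(real = Re(half[length(half)]))
      spec <- c(half, Conj(rev(half[2:(length(half) - 1L)])))
      m <- Re(stats::fft(spec, inverse = TRUE)) / n_grid
      m <- m - mean(m)
      s <- stats::sd(m)
      if (s > 0) m <- m * params$sdnn_target_ms / s
      t_grid <- (seq_along(m) - 1) / fs_mod
      mod_fun <- stats::approxfun(t_grid, m, rule = 2)
      t <- 0.3
      rr <- numeric(0)
      while (TRUE) {
        rr_k <- mean_rr + mod_fun(t)
        rr_k <- min(max(rr_k, 300), 2000)
        t_next <- t + rr_k / 1000
        if (t_next > duration_s - 0.3) break
        rr <- c(rr, rr_k)
        t <- t_next
      }
      realized <- stats::sd(rr) * sqrt((length(rr) - 1) / length(rr))
      if (length(rr) > 10 && realized < 0.5 * params$sdnn_target_ms) {
        warning(sprintf(
          "target SDNN %.1f ms not reachable under [300, 2000] ms clipping; realized %.1f ms",
          params$sdnn_target_ms, realized))
      }
    }
    times <- 0.3 + c(0, cumsum(rr)) / 1000
    structure(list(rr_ms = rr, times_s = times), class = "rr_series")
  })
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms (%.1f bpm), SDNN %.1f ms\n",
              length(x$rr_ms), mean(x$rr_ms), 60000 / mean(x$rr_ms),
              stats::sd(x$rr_ms)))
  invisible(x)
}

#' Default ECG beat template
#'
#' Gaussian bumps approximating lead-II morphology: P, Q, R, S, T waves with
#' amplitude (mV), centre offset from the R peak (s) and Gaussian width (s).
#' Documented constants, not physiological claims.
#'
#' @return data.frame with columns \code{wave}, \code{amp}, \code{center},
#'   \code{width}.
#' @export
default_beat_template <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amp = c(0.18, -0.10, 1.00, -0.15, 0.35),
             center = c(-0.200, -0.030, 0.000, 0.030, 0.250),
             width = c(0.030, 0.012, 0.025, 0.012, 0.060))
}

#' Synthesize a single-lead ECG from an RR series
#'
#' The clean signal is a sum of per-beat Gaussian bumps placed at the RR
#' series' beat times (the R bump centred exactly at each ground-truth R
#' time), to which baseline wander, powerline interference, white noise and
#' motion artifacts are added per \code{noise}. RNG draws occur in a fixed
#' order (baseline phase, powerline phase, white noise, artifacts) so runs
#' with the same seed differ only where parameters differ.
#'
#' @param rr an \code{rr_series} (see \code{\link{generate_rr_series}}).
#' @param fs sampling rate in Hz (>= 100).
#' @param template beat template (see \code{\link{default_beat_template}}).
#' @param noise a \code{\link{noise_params}}.
#' @param seed integer seed or \code{NULL}.
#' @param duration_s record length; defaults to the RR series' span plus the
#'   start offset.
#' @param ... session metadata forwarded to \code{\link{ecg_record}}.
#' @return List with the \code{record} (an \code{ecg_record}) and the
#'   \code{truth} (R-peak times, RR intervals, artifact windows, template).
#' @export
synthesize_ecg <- function(rr, fs = 200, template = default_beat_template(),
                           noise = zero_noise_params(), seed = NULL,
                           duration_s = NULL, ...) {
  stopifnot(inherits(rr, "rr_series"), inherits(noise, "noise_params"))
  check_number(fs, "fs", 100)
  if (any(round(6 * template$width * fs) < 3)) {
    stop_fcg("fs = %g Hz too low to resolve the narrowest template wave (support < 3 samples)", fs)
  }
  if (is.null(duration_s)) duration_s <- max(rr$times_s) + 0.3
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  clean <- numeric(n)
  for (tb in rr$times_s) {
    for (w in seq_len(nrow(template))) {
      c0 <- tb + template$center[w]; wd <- template$width[w]
      i0 <- max(1L, floor((c0 - 5 * wd) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + 5 * wd) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      clean[idx] <- clean[idx] +
        template$amp[w] * exp(-(t[idx] - c0)^2 / (2 * wd^2))
    }
  }
  art_windows <- NULL
  noisy <- with_seed(seed, {
    x <- clean
    ph_b <- stats::runif(1, 0, 2 * pi)
    ph_p <- stats::runif(1, 0, 2 * pi)
    if (noise$baseline_amp_mv > 0) {
      x <- x + noise$baseline_amp_mv * sin(2 * pi * noise$baseline_freq_hz * t + ph_b)
    }
    if (noise$powerline_amp_mv > 0) {
      x <- x + noise$powerline_amp_mv * sin(2 * pi * 50 * t + ph_p)
    }
    if (noise$white_sd_mv > 0) {
      x <- x + stats::rnorm(n, 0, noise$white_sd_mv)
    } else {
      invisible(stats::rnorm(n))  # keep the draw order fixed across settings
    }
    if (noise$artifact_rate_per_min > 0 && noise$artifact_amp_mv > 0) {
      n_art <- stats::rpois(1, noise$artifact_rate_per_min * duration_s / 60)
      if (n_art > 0) {
        starts <- stats::runif(n_art, 0, duration_s - 0.5)
        signs <- sample(c(-1, 1), n_art, replace = TRUE)
        art_windows <- cbind(start_s = starts, end_s = starts + 0.5)
        for (k in seq_len(n_art)) {
          idx <- which(t >= starts[k] & t <= starts[k] + 0.5)
          x[idx] <- x[idx] + signs[k] * noise$artifact_amp_mv * 0.5 *
            (1 - cos(2 * pi * (t[idx] - starts[k]) / 0.5))
        }
      }
    }
    x
  })
  list(record = ecg_record(noisy, fs, ...),
       truth = list(r_times_s = rr$times_s, rr_ms = rr$rr_ms,
                    artifact_windows = art_windows, template = template,
                    clean = clean))
}

#' Default session-to-class assignment rule
#'
#' Class mixing probabilities per session slot: mornings are biased towards
#' normal, evenings towards fatigued, with stochastic mixing so every class
#' occurs in every slot.
#'
#' @return Named list of length-3 probability vectors (normal, slight,
#'   fatigued), one per session slot.
#' @export
default_session_class_rule <- function() {
  list(morning = c(0.60, 0.30, 0.10),
       noon    = c(0.25, 0.50, 0.25),
       evening = c(0.10, 0.30, 0.60))
}

# Borg scores consistent with a class under the default (11, 14) cutoffs.
borg_range_for_class <- function(class) {
  switch(as.character(class),
         normal = 7:11, slight = 12:14, fatigued = 15:18,
         stop_fcg("unknown class %s", class))
}

#' Generate a synthetic multi-subject wearable-ECG study
#'
#' Produces \code{n_subjects x n_days x 3} sessions (morning/noon/evening) of
#' \code{session_duration_s} seconds each. Each session is assigned a fatigue
#' class by \code{session_class_rule}, a Borg score consistent with that
#' class, and an ECG synthesized from class-conditioned RR parameters.
#' Subjects receive a persistent uniform mean-HR offset so subject-wise
#' generalization is harder than segment-wise. Beat morphology carries a
#' class-dependent component (see \code{morphology_by_class}). Generation is
#' a pure function of (configuration, seed).
#'
#' @param n_subjects,n_days study shape (defaults 12 subjects, 14 days).
#' @param class_params named list of per-class \code{synth_class_params}.
#' @param noise a \code{\link{noise_params}}.
#' @param session_class_rule per-slot class probabilities
#'   (see \code{\link{default_session_class_rule}}).
#' @param seed integer seed (required for reproducibility).
#' @param fs sampling rate (Hz).
#' @param session_duration_s session length in seconds (default 600 = 10 min).
#' @param subject_hr_jitter_bpm half-width of the per-subject uniform mean-HR
#'   offset (baseline inter-individual variation).
#' @param session_hr_jitter_bpm half-width of the per-session uniform mean-HR
#'   offset (day-to-day and time-of-day variation within subject).
#' @param hrv_jitter if \code{TRUE} (default), SDNN, vagal tone
#'   (\code{rmssd_scale}) and LF/HF also vary log-uniformly between subjects
#'   (up to about +/- 25\%) and sessions (up to about +/- 12\%), emulating
#'   the large inter-individual spread of real HRV; without it every HRV
#'   feature is an implausibly clean class marker.
#' @param vlf_drift_range range of the within-session very-low-frequency
#'   mean-HR drift amplitude (fraction of mean RR; default 2-8\%, one draw
#'   per session, sinusoidal with a 3-7 min period). Real 10-min recordings
#'   are not stationary; without this drift every 30-s window of a session
#'   shares one tight HRV fingerprint and windowed evaluation is
#'   unrealistically easy. \code{c(0, 0)} disables the drift.
#' @param signals if \code{FALSE}, only the manifest and ground-truth classes
#'   are generated (fast path for design checks).
#' @param waveforms if \code{FALSE} (and \code{signals = TRUE}), RR series
#'   and ground truth are generated but ECG waveform synthesis is skipped —
#'   an order of magnitude faster when only RR-level truth is needed. The
#'   generated RR truth is identical either way.
#' @param morphology_by_class if \code{TRUE} (default), repolarization
#'   morphology co-varies with autonomic state: the T-wave amplitude scales
#'   with the class vagal tone (\code{0.5 + 0.5 rmssd_scale} of the
#'   template value) and the R-to-T interval follows the square root of the
#'   session's mean RR (Bazett-like QT shortening). This puts
#'   class-conditioned information into the raw waveform that R-time-based
#'   HRV features cannot see, emulating why raw-signal classifiers can
#'   outperform feature-based ones on real ECG. The T amplitude additionally
#'   carries a persistent per-subject factor (about +/- 6\%) and a
#'   per-session factor (about +/- 5\%) emulating electrode placement and
#'   skin-contact differences between applications of a wearable patch;
#'   within a session the quirk is constant, so segment-level splits can
#'   exploit it while session- and subject-wise splits cannot.
#' @param dir if non-\code{NULL}, session CSVs, the manifest and a
#'   ground-truth JSON sidecar are written there.
#' @return Object of class \code{synth_study}: \code{manifest}
#'   (a \code{study_manifest}), \code{records} (named list of
#'   \code{ecg_record}, unless \code{signals = FALSE}), \code{truth} (named
#'   list of per-session ground truth), \code{fs}.
#' @export
generate_study <- function(n_subjects = 12, n_days = 14,
                           class_params = default_class_params(),
                           noise = noise_params(),
                           session_class_rule = default_session_class_rule(),
                           seed = 1, fs = 200, session_duration_s = 600,
                           subject_hr_jitter_bpm = 9, session_hr_jitter_bpm = 4,
                           hrv_jitter = TRUE, vlf_drift_range = c(0.02, 0.08),
                           signals = TRUE, waveforms = TRUE,
                           morphology_by_class = TRUE, dir = NULL) {
  check_number(n_subjects, "n_subjects", 1)
  check_number(n_days, "n_days", 1)
  stopifnot(setequal(names(class_params), fatigue_levels()))
  with_seed(seed, {
    subjects <- sprintf("s%02d", seq_len(n_subjects))
    hr_offset <- stats::runif(n_subjects, -subject_hr_jitter_bpm,
                              subject_hr_jitter_bpm)
    names(hr_offset) <- subjects
    lunif <- function(n, spread) exp(stats::runif(n, -log(spread), log(spread)))
    sub_sdnn_f <- lunif(n_subjects, if (hrv_jitter) 1.25 else 1)
    sub_rmssd_f <- lunif(n_subjects, if (hrv_jitter) 1.2 else 1)
    sub_lfhf_f <- lunif(n_subjects, if (hrv_jitter) 1.4 else 1)
    sub_tamp_f <- lunif(n_subjects, if (morphology_by_class) 1.04 else 1)
    # subject-specific waveform shape (electrode geometry, anatomy): width
    # and timing quirks orthogonal to the class-carrying T/R amplitude ratio
    sub_twidth_f <- lunif(n_subjects, if (morphology_by_class) 1.15 else 1)
    sub_tcenter_f <- lunif(n_subjects, if (morphology_by_class) 1.08 else 1)
    sub_pamp_f <- lunif(n_subjects, if (morphology_by_class) 1.25 else 1)
    names(sub_sdnn_f) <- names(sub_rmssd_f) <- names(sub_lfhf_f) <-
      names(sub_tamp_f) <- names(sub_twidth_f) <- names(sub_tcenter_f) <-
      names(sub_pamp_f) <- subjects
    grid <- expand.grid(session = session_levels(), day = seq_len(n_days),
                        subject_id = subjects, stringsAsFactors = FALSE)
    grid <- grid[, c("subject_id", "day", "session")]
    n_sess <- nrow(grid)
    cls <- character(n_sess)
    borg <- integer(n_sess)
    for (i in seq_len(n_sess)) {
      p <- session_class_rule[[grid$session[i]]]
      cls[i] <- sample(fatigue_levels(), 1, prob = p)
      borg[i] <- sample(borg_range_for_class(cls[i]), 1)
    }
    sess_offset <- stats::runif(n_sess, -session_hr_jitter_bpm,
                                session_hr_jitter_bpm)
    sess_sdnn_f <- lunif(n_sess, if (hrv_jitter) 1.12 else 1)
    sess_lfhf_f <- lunif(n_sess, if (hrv_jitter) 1.18 else 1)
    sess_tamp_f <- lunif(n_sess, if (morphology_by_class) 1.03 else 1)
    sess_twidth_f <- lunif(n_sess, if (morphology_by_class) 1.05 else 1)
    sess_pamp_f <- lunif(n_sess, if (morphology_by_class) 1.10 else 1)
    sub_seeds <- sample.int(2^31 - 2, n_sess)
    records <- list()
    truth <- list()
    key <- sprintf("%s_d%02d_%s", grid$subject_id, grid$day, grid$session)
    if (signals) {
      for (i in seq_len(n_sess)) {
        p0 <- class_params[[cls[i]]]
        sid <- grid$subject_id[i]
        hr_i <- p0$mean_hr_bpm + hr_offset[sid] + sess_offset[i]
        p <- synth_class_params(hr_i,
                                p0$sdnn_target_ms * sub_sdnn_f[sid] * sess_sdnn_f[i],
                                p0$lf_hf_ratio * sub_lfhf_f[sid] * sess_lfhf_f[i],
                                p0$rmssd_scale * sub_rmssd_f[sid])
        rr <- generate_rr_series(p, session_duration_s, seed = sub_seeds[i])
        if (max(vlf_drift_range) > 0) {
          damp <- stats::runif(1, vlf_drift_range[1], vlf_drift_range[2])
          dper <- stats::runif(1, 180, 420)
          dphi <- stats::runif(1, 0, 2 * pi)
          tmid <- rr$times_s[-length(rr$times_s)]
          rr$rr_ms <- pmin(2000, pmax(300, rr$rr_ms *
            (1 + damp * sin(2 * pi * tmid / dper + dphi))))
          rr$times_s <- rr$times_s[1] + c(0, cumsum(rr$rr_ms)) / 1000
          # drift changes total span; drop beats pushed past the session end
          keep <- rr$times_s <= session_duration_s - 0.3
          rr$times_s <- rr$times_s[keep]
          rr$rr_ms <- rr$rr_ms[keep[-1]]
        }
        tpl <- default_beat_template()
        if (morphology_by_class) {
          tw <- tpl$wave == "T"
          pw <- tpl$wave == "P"
          tpl$amp[tw] <- tpl$amp[tw] * (0.5 + 0.5 * p0$rmssd_scale) *
            sub_tamp_f[sid] * sess_tamp_f[i]
          tpl$center[tw] <- tpl$center[tw] * sqrt(mean(rr$rr_ms) / 900) *
            sub_tcenter_f[sid]
          tpl$width[tw] <- tpl$width[tw] * sub_twidth_f[sid] * sess_twidth_f[i]
          tpl$amp[pw] <- tpl$amp[pw] * sub_pamp_f[sid] * sess_pamp_f[i]
        }
        if (waveforms) {
          out <- synthesize_ecg(rr, fs = fs, template = tpl, noise = noise,
                                seed = sub_seeds[i] %% (2^31 - 3) + 1,
                                duration_s = session_duration_s,
                                subject_id = grid$subject_id[i],
                                day = grid$day[i], session = grid$session[i],
                                borg_score = borg[i])
          out$truth$clean <- NULL  # keep study objects light
          records[[key[i]]] <- out$record
          truth[[key[i]]] <- c(out$truth, list(class = cls[i]))
        } else {
          # synthesize_ecg is internally seeded, so skipping it leaves the
          # generation stream (and hence the RR truth) unchanged
          truth[[key[i]]] <- list(r_times_s = rr$times_s, rr_ms = rr$rr_ms,
                                  template = tpl, class = cls[i])
        }
      }
    } else {
      truth <- lapply(seq_len(n_sess), function(i) list(class = cls[i]))
      names(truth) <- key
    }
    manifest <- data.frame(subject_id = grid$subject_id, day = grid$day,
                           session = grid$session, borg = borg,
                           path = if (is.null(dir)) "" else paste0(key, ".csv"),
                           stringsAsFactors = FALSE)
    manifest <- as_manifest(manifest)
    manifest$key <- key
    study <- structure(list(manifest = manifest, records = records,
                            truth = truth, fs = fs,
                            session_duration_s = session_duration_s,
                            seed = seed),
                       class = "synth_study")
    if (!is.null(dir)) write_study(study, dir)
    study
  })
}

#' @export
print.synth_study <- function(x, ...) {
  tab <- table(vapply(x$truth, `[[`, "", "class"))
  cat(sprintf("<synth_study> %d sessions (%d with signals) @ %g Hz, %g s each\n",
              nrow(x$manifest), length(x$records), x$fs, x$session_duration_s))
  cat("  class counts:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes one CSV sample file per session, the manifest CSV and a
#' ground-truth JSON sidecar (R-peak times, RR intervals, class per session).
#'
#' @param study a \code{synth_study} generated with \code{signals = TRUE}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(study$records)) {
    write_ecg(study$records[[key]], file.path(dir, paste0(key, ".csv")))
  }
  m <- study$manifest
  m$path <- paste0(m$key, ".csv")
  write_manifest(m, file.path(dir, "manifest.csv"))
  gt <- lapply(study$truth, function(tr) {
    list(class = tr$class, r_times_s = tr$r_times_s, rr_ms = tr$rr_ms)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a study written by \code{\link{write_study}}
#' @param dir directory containing \code{manifest.csv}.
#' @return A \code{synth_study} (without ground truth unless the sidecar is
#'   present).
#' @export
read_study <- function(dir) {
  manifest <- load_manifest(file.path(dir, "manifest.csv"))
  manifest$key <- sub("\\.csv$", "", basename(manifest$path))
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    records[[manifest$key[i]]] <-
      read_ecg(manifest$path[i], subject_id = manifest$subject_id[i],
               day = manifest$day[i], session = manifest$session[i],
               borg_score = manifest$borg[i])
  }
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  fs <- if (length(records)) records[[1]]$fs else 200
  structure(list(manifest = manifest, records = records, truth = truth,
                 fs = fs,
                 session_duration_s = if (length(records)) records[[1]]$duration_s else NA),
            class = "synth_study")
}
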