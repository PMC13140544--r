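## Zero-phase FIR anti-aliased resampling to fs_target: forward-backward
## low-pass below the new Nyquist, then interpolation onto the target
## sample grid. Identity when fs == fs_target.
resample_zero_phase <- function(x, fs, fs_target) {
  if (fs == fs_target) return(x)
  if (fs < fs_target) stopf("resample: fs (%g) below target (%g)", fs, fs_target)
  ny_new <- fs_target / 2
  b <- signal::fir1(128, (0.9 * ny_new) / (fs / 2), type = "low")
  xf <- signal::filtfilt(as.numeric(b), 1, x)
  t_old <- (seq_along(x) - 1) / fs
  n_new <- floor(t_old[length(t_old)] * fs_target) + 1
  t_new <- (seq_len(n_new) - 1) / fs_target
  approx(t_old, xf, xout = t_new)$y
}

## Zero-phase Butterworth high-pass.
highpass_zero_phase <- function(x, fs, cutoff_hz, order = 2) {
  bt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  signal::filtfilt(bt, x)
}

## Zero-phase notch filters at base and harmonics strictly below Nyquist.
notch_harmonics <- function(x, fs, base_hz = 50, max_hz = 400, halfwidth_hz = 2) {
  freqs <- seq(base_hz, max_hz, by = base_hz)
  freqs <- freqs[freqs < 0.98 * fs / 2]
  for (f0 in freqs) {
    bt <- signal::butter(2, c(f0 - halfwidth_hz, f0 + halfwidth_hz) / (fs / 2),
                         type = "stop")
    x <- signal::filtfilt(bt, x)
  }
  x
}

#' Condition LFP and EMG signals
#'
#' LFP: anti-aliased zero-phase decimation to the analysis rate,
#' zero-phase 0.5 Hz high-pass, zero-phase notch at 50 Hz and harmonics
#' below the analysis Nyquist. EMG: decimation, mean removal, zero-phase
#' 10 Hz high-pass, full-wave rectification. All filtering is
#' forward-backward, so event timing is unbiased by filtering.
#'
#' @param rec a `lead_recording`.
#' @param cfg a `preproc_config`.
#' @return the conditioned `lead_recording` (fs = `cfg$fs_target`,
#'   `emg` rectified).
#' @export
condition_signals <- function(rec, cfg = preproc_config()) {
  if (rec$fs < cfg$fs_target)
    stopf("condition_signals: fs (%g) below fs_target (%g)", rec$fs, cfg$fs_target)
  fs <- cfg$fs_target
  lfp <- t(apply(rec$lfp, 1, function(x) {
    x <- resample_zero_phase(x, rec$fs, fs)
    x <- highpass_zero_phase(x, fs, cfg$lfp_highpass_hz)
    notch_harmonics(x, fs, cfg$notch_base_hz, cfg$notch_max_hz, cfg$notch_halfwidth_hz)
  }))
  emg <- resample_zero_phase(rec$emg, rec$fs, fs)
  emg <- emg - mean(emg)
  emg <- abs(highpass_zero_phase(emg, fs, cfg$emg_highpass_hz))
  rec$lfp <- lfp
  rec$emg <- emg
  rec$fs <- fs
  rec$conditioned <- TRUE
  rec
}

#' Detect EMG bursts around auditory cues
#'
#' For each cue, the onset is the first time after the cue at which the
#' 20 ms moving-average of the rectified EMG exceeds baseline
#' mean + `onset_k` x SD for at least `onset_sustain_ms`; the offset is
#' the end of the descending phase, i.e. the last suprathreshold sample
#' of that burst. The baseline is the pre-cue window
#' `cue + premove_window`. Cues without a qualifying burst are flagged as
#' artifact trials.
#'
#' @param emg_rect rectified EMG vector.
#' @param fs sampling rate, Hz.
#' @param cue_times cue times, s.
#' @param cfg a `preproc_config`.
#' @param max_latency_s latest admissible onset after the cue (default 2.5).
#' @return event data.frame (`cue_time`, `emg_onset`, `emg_offset`,
#'   `artifact`).
#' @export
detect_emg_bursts <- function(emg_rect, fs, cue_times, cfg = preproc_config(),
                              max_latency_s = 2.5) {
  if (length(cue_times) == 0) stopf("detect_emg_bursts: no cues given")
  k <- max(1L, round(cfg$emg_smooth_ms / 1000 * fs))
  sm <- as.numeric(stats::filter(emg_rect, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  sustain <- max(1L, round(cfg$onset_sustain_ms / 1000 * fs))
  n <- length(sm)
  tt <- (seq_len(n) - 1) / fs
  out <- data.frame(cue_time = cue_times, emg_onset = NA_real_,
                    emg_offset = NA_real_, artifact = FALSE)
  for (i in seq_along(cue_times)) {
    cue <- cue_times[i]
    ib <- which(tt >= cue + cfg$premove_window[1] & tt <= cue + cfg$premove_window[2])
    if (length(ib) < 5) { out$artifact[i] <- TRUE; next }
    thr <- mean(sm[ib]) + cfg$onset_k * sd(sm[ib])
    iw <- which(tt > cue & tt <= cue + max_latency_s)
    above <- sm[iw] > thr
    ## first index where `above` holds for `sustain` consecutive samples
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cand <- which(r$values & r$lengths >= sustain)
    if (length(cand) == 0) { out$artifact[i] <- TRUE; next }
    on_idx <- iw[starts[cand[1]]]
    ## back-track to the start of the rising phase: first sample of the
    ## run that stays above baseline mean + 0.5 SD
    thr_lo <- mean(sm[ib]) + 0.5 * sd(sm[ib])
    while (on_idx > iw[1] && sm[on_idx - 1] > thr_lo) on_idx <- on_idx - 1
    ## sub-threshold refinement: smooth burst envelopes rise ~quadratically,
    ## so sqrt(activity above baseline) is locally linear in time --
    ## extrapolate its fitted line back to zero to locate the true rise
    on_t <- tt[on_idx]
    iw2 <- on_idx:min(on_idx + round(0.1 * fs), n)
    if (length(iw2) > 5) {
      u <- sqrt(pmax(sm[iw2] - mean(sm[ib]), 0))
      cf <- coef(stats::lm.fit(cbind(1, tt[iw2]), u))
      if (is.finite(cf[2]) && cf[2] > 0) {
        root <- -cf[1] / cf[2]
        if (is.finite(root)) on_t <- min(on_t, max(on_t - 0.1, root))
      }
    }
    ## offset: last suprathreshold sample of the burst (threshold recross)
    off_rel <- ends[cand[1]]
    ## extend through later runs separated by sub-sustain gaps (one burst)
    j <- cand[1]
    while (j + 2 <= length(r$values) && !r$values[j + 1] &&
           r$lengths[j + 1] < sustain && r$values[j + 2]) {
      j <- j + 2
      off_rel <- ends[j]
    }
    ## forward-track the descending phase down to the 0.5 SD level
    off_idx <- iw[min(off_rel, length(iw))]
    while (off_idx < n && sm[off_idx + 1] > thr_lo) off_idx <- off_idx + 1
    ## mirror-image refinement of the descending tail (see onset)
    off_t <- tt[off_idx]
    iw3 <- max(1, off_idx - round(0.1 * fs)):off_idx
    if (length(iw3) > 5) {
      u <- sqrt(pmax(sm[iw3] - mean(sm[ib]), 0))
      cf <- coef(stats::lm.fit(cbind(1, tt[iw3]), u))
      if (is.finite(cf[2]) && cf[2] < 0) {
        root <- -cf[1] / cf[2]
        if (is.finite(root)) off_t <- max(off_t, min(off_t + 0.1, root))
      }
    }
    out$emg_onset[i] <- on_t
    out$emg_offset[i] <- off_t
  }
  out
}

#' Segment a conditioned recording into trial epochs
#'
#' One epoch per non-artifact trial, spanning `trial_pre_s` before EMG
#' onset to `trial_post_offset_s` after EMG offset; time 0 is the EMG
#' onset. Epochs clipped by the recording edges are dropped and logged.
#'
#' @param rec conditioned `lead_recording`.
#' @param events validated event table.
#' @param cfg a `preproc_config`.
#' @return list with `epochs` (list of `trial_epoch`: `lfp` 8 x n, `emg`,
#'   `time` s relative to onset, `movement_duration_s`, `cue_time`,
#'   `trial`) and `dropped` (data.frame log).
#' @export
segment_trials <- function(rec, events, cfg = preproc_config()) {
  fs <- rec$fs
  n <- ncol(rec$lfp)
  epochs <- list()
  dropped <- data.frame(trial = integer(0), reason = character(0))
  for (i in seq_len(nrow(events))) {
    if (isTRUE(events$artifact[i])) {
      dropped <- rbind(dropped, data.frame(trial = i, reason = "artifact_event"))
      next
    }
    on <- events$emg_onset[i]; off <- events$emg_offset[i]
    i0 <- round((on - cfg$trial_pre_s) * fs) + 1
    i1 <- round((off + cfg$trial_post_offset_s) * fs) + 1
    if (i0 < 1 || i1 > n) {
      dropped <- rbind(dropped, data.frame(trial = i, reason = "clipped_at_edge"))
      next
    }
    idx <- i0:i1
    epochs[[length(epochs) + 1]] <- structure(list(
      hemisphere_id = rec$hemisphere_id, trial = i,
      lfp = rec$lfp[, idx, drop = FALSE], emg = rec$emg[idx],
      time = (idx - 1) / fs - on, movement_duration_s = off - on,
      cue_time = events$cue_time[i] - on), class = "trial_epoch")
  }
  list(epochs = epochs, dropped = dropped)
}

#' Reject artifact trials
#'
#' A trial is rejected when any LFP channel's peak absolute amplitude is
#' a robust outlier across trials: robust z = (peak - median) / MAD of
#' that channel's per-trial peaks exceeds `artifact_z_thresh`.
#'
#' @param epochs list of `trial_epoch`.
#' @param cfg a `preproc_config`.
#' @return list with `kept` (epochs) and `log` (data.frame: trial,
#'   channel, z, reason).
#' @export
reject_artifact_trials <- function(epochs, cfg = preproc_config()) {
  if (length(epochs) == 0) stopf("reject_artifact_trials: no epochs")
  peaks <- t(vapply(epochs, function(e) apply(abs(e$lfp), 1, max), numeric(8)))
  med <- apply(peaks, 2, median)
  madv <- apply(peaks, 2, mad)
  madv[madv < 1e-12] <- 1e-12
  z <- sweep(sweep(peaks, 2, med), 2, madv, `/`)
  bad <- apply(z, 1, function(r) any(r > cfg$artifact_z_thresh))
  log <- data.frame(trial = integer(0), channel = integer(0), z = numeric(0),
                    reason = character(0))
  for (i in which(bad)) {
    ch <- which.max(z[i, ])
    log <- rbind(log, data.frame(trial = epochs[[i]]$trial, channel = ch,
                                 z = z[i, ch], reason = "peak_amplitude_outlier"))
  }
  kept <- epochs[!bad]
  if (length(kept) == 0)
    stopf("reject_artifact_trials: all trials rejected for hemisphere %s",
          epochs[[1]]$hemisphere_id)
  list(kept = kept, log = log)
}

#' Full preprocessing of one raw recording
#'
#' Condition signals, detect EMG bursts from the recorded cues, validate
#' events, segment and reject artifact trials.
#'
#' @param rec raw `lead_recording`.
#' @param cfg a `preproc_config`.
#' @param use_true_events if TRUE, use the event table carried by the
#'   recording instead of detecting bursts (generator truth).
#' @return list with `rec` (conditioned), `events`, `epochs`, `dropped`,
#'   `rejection_log`.
#' @export
preprocess_recording <- function(rec, cfg = preproc_config(),
                                 use_true_events = FALSE) {
  crec <- condition_signals(rec, cfg)
  if (use_true_events) {
    events <- rec$events
  } else {
    events <- detect_emg_bursts(crec$emg, crec$fs, rec$events$cue_time, cfg)
  }
  ok <- !events$artifact
  if (any(ok)) validate_events(events[ok, , drop = FALSE])
  seg <- segment_trials(crec, events, cfg)
  if (length(seg$epochs) == 0)
    stopf("preprocess_recording: no usable trials for %s", rec$hemisphere_id)
  rej <- reject_artifact_trials(seg$epochs, cfg)
  list(rec = crec, events = events, epochs = rej$kept, dropped = seg$dropped,
       rejection_log = rej$log)
}
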