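test_that("conditioning attenuates mains noise and removes DC", {
  set.seed(1)
  fs <- 2048
  n <- fs * 20
  tt <- (0:(n - 1)) / fs
  line <- sin(2 * pi * 50 * tt)
  rec <- structure(list(hemisphere_id = "h", fs = fs,
                        lfp = matrix(rep(line + 3, 8), nrow = 8, byrow = TRUE),
                        emg = rnorm(n),
                        events = data.frame(cue_time = 5, emg_onset = 5.4,
                                            emg_offset = 6.5, artifact = FALSE),
                        contacts = NULL, side = "right"),
                   class = "lead_recording")
  out <- condition_signals(rec, preproc_config())
  expect_equal(out$fs, 800)
  ## wide margins: the 0.5 Hz high-pass response to the DC step decays slowly
  core <- 3200:(ncol(out$lfp) - 3200)
  p_in <- mean(resample_zero_phase(line, fs, 800)[core]^2)
  p_out <- mean(out$lfp[1, core]^2)
  expect_gt(10 * log10(p_in / p_out), 40)           # >= 40 dB at 50 Hz
  expect_lt(abs(mean(out$lfp[1, core])), 0.02)      # DC removed
  expect_true(all(out$emg >= 0))                    # rectified
})

test_that("decimation is the identity at the target rate and errors below it", {
  x <- rnorm(1000)
  expect_identical(resample_zero_phase(x, 800, 800), x)
  expect_error(resample_zero_phase(x, 400, 800), "below")
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  fs <- 800
  n <- 4001
  x <- exp(-((seq_len(n) - 2001) / 80)^2)          # symmetric Gaussian pulse
  y <- highpass_zero_phase(x, fs, 0.5)
  y <- notch_harmonics(y, fs)
  expect_equal(which.max(y), 2001, tolerance = 1)
  ## symmetry about the peak (mirrored index order)
  expect_equal(y[2001 + 1:500], y[2001 - 1:500], tolerance = 1e-4)
})

test_that("EMG onset detection recovers planted burst onsets within 25 ms", {
  set.seed(41)
  fs <- 800
  n <- fs * 710
  tt <- (0:(n - 1)) / fs
  car <- band_carrier(n, fs, 30, 350)
  env <- rep(0.08, n)
  cues <- seq(8, 8 + 3.5 * 199, by = 3.5)  # 200 bursts, 3.5 s apart
  true_on <- cues + 0.4
  for (k in seq_along(cues)) {
    idx <- which(tt >= true_on[k] & tt <= true_on[k] + 1.2)
    env[idx] <- 0.08 + raised_cosine_bump((tt[idx] - true_on[k]) / 1.2, 0.29)
  }
  cfg <- preproc_config(premove_window = c(-1.2, -0.2))
  ev <- detect_emg_bursts(abs(env * car), fs, cues, cfg)
  expect_equal(sum(ev$artifact), 0)
  err <- ev$emg_onset - true_on
  expect_lte(mean(abs(err)) * 1000, 25)
})

test_that("flat EMG yields zero bursts, all trials flagged", {
  set.seed(5)
  ev <- detect_emg_bursts(abs(rnorm(800 * 60, 0, 0.05)), 800, c(10, 20, 30, 40))
  expect_true(all(ev$artifact))
  expect_true(all(is.na(ev$emg_onset)))
  expect_error(detect_emg_bursts(rnorm(100), 800, numeric(0)), "no cues")
})

test_that("cue-to-onset delays are recovered at the cohort scale", {
  f <- fixture_recording(seed = 31, n_trials = 16, rest_s = 15)
  pre <- preprocess_recording(f$sim$recording, preproc_config())
  keep <- !pre$events$artifact
  true_delay <- f$sim$truth$events$emg_onset - f$sim$truth$events$cue_time
  det_delay <- pre$events$emg_onset[keep] - pre$events$cue_time[keep]
  expect_gt(mean(keep), 0.8)
  expect_lt(abs(mean(det_delay) - mean(true_delay[keep])), 0.05)
})

test_that("segmentation spans [-3, offset + 2] s and drops clipped epochs", {
  fs <- 800
  rec <- structure(list(hemisphere_id = "h", fs = fs,
                        lfp = matrix(rnorm(8 * fs * 20), nrow = 8),
                        emg = abs(rnorm(fs * 20)), side = "right"),
                   class = "lead_recording")
  events <- data.frame(cue_time = c(0.5, 9.6), emg_onset = c(1, 10),
                       emg_offset = c(2.2, 11.5), artifact = FALSE)
  seg <- segment_trials(rec, events, preproc_config())
  ## first trial needs samples at -3 s before onset = -2 s -> clipped
  expect_length(seg$epochs, 1)
  expect_equal(seg$dropped$reason, "clipped_at_edge")
  e <- seg$epochs[[1]]
  expect_equal(e$time[1], -3, tolerance = 1e-2)
  expect_equal(max(e$time), 1.5 + 2, tolerance = 1e-2)
  expect_equal(e$movement_duration_s, 1.5)
  ## kept + dropped = total
  expect_equal(length(seg$epochs) + nrow(seg$dropped), nrow(events))
})

test_that("artifact rejection removes exactly the poisoned trial", {
  set.seed(6)
  epochs <- lapply(1:12, function(i) structure(list(
    hemisphere_id = "h", trial = i, lfp = matrix(rnorm(8 * 400), 8),
    emg = abs(rnorm(400)), time = seq(-1, 1, length.out = 400),
    movement_duration_s = 1, cue_time = -0.4), class = "trial_epoch"))
  clean <- reject_artifact_trials(epochs, preproc_config())
  expect_lte(nrow(clean$log), 1)   # clean data: at most a chance outlier
  epochs[[7]]$lfp[3, 100] <- 10 * max(abs(epochs[[7]]$lfp))
  rej <- reject_artifact_trials(epochs, preproc_config())
  expect_true(7 %in% rej$log$trial)
  expect_gte(length(rej$kept), 10)
  expect_error(reject_artifact_trials(list(), preproc_config()), "no epochs")
})

test_that("kept-trial count matches the planted artifact rate", {
  ## 20 attempted trials with a 10% planted artifact rate -> ~18 kept,
  ## the neighbourhood of the per-block trial counts such recordings give
  set.seed(8)
  counts <- vapply(1:30, function(r) {
    epochs <- lapply(1:20, function(i) structure(list(
      hemisphere_id = "h", trial = i, lfp = matrix(rnorm(8 * 300), 8),
      emg = abs(rnorm(300)), time = seq(-1, 1, length.out = 300),
      movement_duration_s = 1, cue_time = -0.4), class = "trial_epoch"))
    for (i in sample(20, 2))
      epochs[[i]]$lfp[sample(8, 1), 50] <- 40
    length(reject_artifact_trials(epochs, preproc_config())$kept)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 18), 0.6)
})
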