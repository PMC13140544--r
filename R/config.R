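#' Spectral sub-band definitions
#'
#' Frequency sub-bands used throughout the pipeline: beta (13-30 Hz),
#' high-gamma HG (60-90 Hz), fast-gamma FG (110-140 Hz), slow
#' high-frequency oscillations SHFO (202-298 Hz) and fast HFO FHFO
#' (302-390 Hz). Beta is analysed on the low-frequency multitaper range,
#' the four high-frequency bands on the high range.
#'
#' @param which "all" (default), "high" (the four bands above 50 Hz) or
#'   "beta".
#' @return A data.frame with columns `band`, `f_lo`, `f_hi`, `range`
#'   (`"low"` or `"high"`).
#' @export
stn_bands <- function(which = c("all", "high", "beta")) {
  which <- match.arg(which)
  b <- data.frame(
    band  = c("beta", "HG", "FG", "SHFO", "FHFO"),
    f_lo  = c(13, 60, 110, 202, 302),
    f_hi  = c(30, 90, 140, 298, 390),
    range = c("low", "high", "high", "high", "high"),
    stringsAsFactors = FALSE
  )
  switch(which, all = b, high = b[b$range == "high", ], beta = b[b$band == "beta", ])
}

#' Multitaper spectral configuration
#'
#' Two analysis ranges: low (10-50 Hz), 400 ms windows stepped by 10 ms
#' with +/- 2 Hz spectral smoothing (2.5 Hz frequency spacing at 800 Hz),
#' and high (50-395 Hz), 200 ms windows stepped by 10 ms with +/- 10 Hz
#' smoothing (5 Hz spacing). The movement period is normalized onto a
#' 0-100% grid in 5% bins; rest and pre-movement states are summarized in
#' 100 ms epochs.
#'
#' @param fs_target analysis sampling rate, Hz.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(fs_target = 800) {
  cfg <- list(
    fs_target = fs_target,
    low  = list(f_lo = 10, f_hi = 50,  window_s = 0.4, step_s = 0.01, half_bw_hz = 2),
    high = list(f_lo = 50, f_hi = 395, window_s = 0.2, step_s = 0.01, half_bw_hz = 10),
    move_grid = seq(0, 100, by = 5),    # percent of movement, 21 points
    state_epoch_s = 0.1,                # rest / pre-movement epoch length
    bands = stn_bands()
  )
  class(cfg) <- "spectral_config"
  cfg
}

#' Preprocessing configuration
#'
#' Defaults: analysis rate 800 Hz; LFP high-pass 0.5 Hz and notch at 50 Hz
#' harmonics below Nyquist; EMG high-pass 10 Hz then rectification; trials
#' span 3 s before EMG onset to 2 s after EMG offset; baseline window
#' (-3, -2) s relative to onset; pre-movement window (-1.5, -0.2) s
#' relative to the cue (disjoint from the baseline). EMG onset detection:
#' 20 ms moving-average smoothed rectified EMG crossing baseline
#' mean + onset_k * SD sustained for onset_sustain_ms. Artifact rule:
#' per-channel peak-amplitude robust z (across-trial median/MAD) above
#' artifact_z_thresh rejects the trial.
#'
#' @param ... named overrides of any default field.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(...) {
  cfg <- list(
    fs_target = 800,
    lfp_highpass_hz = 0.5,
    emg_highpass_hz = 10,
    notch_base_hz = 50,
    notch_max_hz = 400,
    notch_halfwidth_hz = 2,
    trial_pre_s = 3,
    trial_post_offset_s = 2,
    baseline_window = c(-3, -2),     # s relative to EMG onset
    premove_window = c(-1.5, -0.2),  # s relative to cue
    emg_smooth_ms = 20,
    onset_k = 3,
    onset_sustain_ms = 50,
    artifact_z_thresh = 5
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stopf("unknown preproc_config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$baseline_window[1] >= cfg$baseline_window[2])
    stopf("baseline_window must be increasing")
  class(cfg) <- "preproc_config"
  cfg
}

#' Statistical-inference configuration
#'
#' @param n_bootstrap bootstrap resamples for correlation CIs (default 5000).
#' @param ci_level confidence level (default 0.95).
#' @param alpha significance level (default 0.05).
#' @param n_surrogates random-contact surrogate draws (default 1000).
#' @param n_shuffles shuffles for cross-correlation standardization
#'   (default 1000).
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(n_bootstrap = 5000, ci_level = 0.95, alpha = 0.05,
                         n_surrogates = 1000, n_shuffles = 1000) {
  structure(list(n_bootstrap = n_bootstrap, ci_level = ci_level, alpha = alpha,
                 n_surrogates = n_surrogates, n_shuffles = n_shuffles),
            class = "stats_config")
}

#' Boosting configuration
#'
#' Hyperparameter search ranges follow the clinical-ranking stage:
#' learning rate within (0.3, 0.6) and number of boosting cycles within
#' (30, 200); the inner grid spans those ranges. Base learners are
#' depth-limited regression trees.
#'
#' @param learn_rates grid of learning rates searched per fold.
#' @param n_cycles_grid grid of boosting-cycle counts searched per fold.
#' @param max_depth base-tree depth (default 2).
#' @param n_permutations label shuffles for the importance null (default 1000).
#' @param inner_folds inner cross-validation folds for per-fold
#'   hyperparameter selection (default 3).
#' @param n_rank_replicates seed replicates for top-rank probabilities
#'   (default 100).
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(learn_rates = c(0.3, 0.45, 0.6),
                         n_cycles_grid = c(30, 75, 120, 200),
                         max_depth = 2, n_permutations = 1000,
                         inner_folds = 3, n_rank_replicates = 100) {
  if (any(learn_rates < 0.3 - 1e-9) || any(learn_rates > 0.6 + 1e-9))
    stopf("learn_rates must lie within (0.3, 0.6)")
  if (any(n_cycles_grid < 30) || any(n_cycles_grid > 200))
    stopf("n_cycles_grid must lie within (30, 200)")
  structure(list(learn_rates = learn_rates, n_cycles_grid = sort(n_cycles_grid),
                 max_depth = max_depth, n_permutations = n_permutations,
                 inner_folds = inner_folds, n_rank_replicates = n_rank_replicates),
            class = "boost_config")
}
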