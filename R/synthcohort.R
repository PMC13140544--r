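#' Band-limited source specification
#'
#' One planted oscillatory source: a band-limited noise carrier with a
#' spatially localized Gaussian gain profile whose center may move across
#' behavioural states (rest -> pre-movement -> movement start -> movement
#' end; within the movement the center is interpolated linearly, planting
#' hotspot propagation), and a movement-locked amplitude envelope
#' (raised-cosine bump peaking at `move_envelope_peak_frac` of the
#' movement). `polarity = -1` plants desynchronization (amplitude dip,
#' beta-style ERD) instead of synchronization.
#'
#' @param band_name label (must match an analysis band to be recovered).
#' @param f_lo,f_hi carrier band edges, Hz.
#' @param center_rest,center_premove,center_move_start,center_move_end
#'   3-vectors, mm (hotspot trajectory).
#' @param spatial_sigma Gaussian gain width, mm.
#' @param amp_rest,amp_premove dimensionless gains.
#' @param move_envelope_peak_frac peak position as a fraction of movement
#'   duration, in `[0, 1]`.
#' @param move_envelope_gain envelope amplitude (added to `amp_rest` with
#'   sign `polarity` during movement).
#' @param polarity `+1` (ERS) or `-1` (ERD).
#' @param random_shift_mm magnitude of an additional per-hemisphere
#'   movement shift with random direction in the x-z plane (models
#'   propagation without a consistent group-level direction; default 0).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(band_name, f_lo, f_hi,
                        center_rest, center_premove = center_rest,
                        center_move_start = center_premove,
                        center_move_end = center_move_start,
                        spatial_sigma = 1.5, amp_rest = 1, amp_premove = amp_rest,
                        move_envelope_peak_frac = 0.45, move_envelope_gain = 1,
                        polarity = 1, random_shift_mm = 0) {
  if (!(f_lo < f_hi)) stopf("source_spec: f_lo must be < f_hi")
  if (spatial_sigma <= 0) stopf("source_spec: spatial_sigma must be > 0")
  if (move_envelope_peak_frac < 0 || move_envelope_peak_frac > 1)
    stopf("source_spec: move_envelope_peak_frac must lie in [0, 1]")
  if (!polarity %in% c(-1, 1)) stopf("source_spec: polarity must be +1 or -1")
  structure(list(band_name = band_name, f_lo = f_lo, f_hi = f_hi,
                 center_rest = as.numeric(center_rest),
                 center_premove = as.numeric(center_premove),
                 center_move_start = as.numeric(center_move_start),
                 center_move_end = as.numeric(center_move_end),
                 spatial_sigma = spatial_sigma, amp_rest = amp_rest,
                 amp_premove = amp_premove,
                 move_envelope_peak_frac = move_envelope_peak_frac,
                 move_envelope_gain = move_envelope_gain, polarity = polarity,
                 random_shift_mm = random_shift_mm),
            class = "source_spec")
}

#' Default planted sources
#'
#' Five sources matching the analysis sub-bands. Envelope peak fractions
#' (EMG-relative timing), the beta desynchronization trough, and the
#' band-specific movement shifts (HG +1.18 mm superior, FG +0.84 mm
#' superior, SHFO mildly inferior, FHFO directionless) encode the planted
#' ground truth the pipeline is expected to recover.
#'
#' @param stn_center STN center, mm.
#' @return list of `source_spec`.
#' @export
default_sources <- function(stn_center = c(12, -13, -7)) {
  sc <- stn_center
  list(
    source_spec("beta", 13, 30,
                center_rest = sc + c(0, 0, 1),
                spatial_sigma = 1.8, amp_rest = 2.5, amp_premove = 2.4,
                move_envelope_peak_frac = 0.14, move_envelope_gain = 2.0,
                polarity = -1),
    source_spec("HG", 60, 90,
                center_rest = sc + c(0, 0, 0.2),
                center_premove = sc + c(0, 0, 0.5),
                center_move_start = sc + c(0, 0, 0.5),
                center_move_end = sc + c(0, 0, 0.5) + c(0, 0, 1.18),
                spatial_sigma = 1.5, amp_rest = 0.7, amp_premove = 0.8,
                move_envelope_peak_frac = 0.44, move_envelope_gain = 1.6),
    source_spec("FG", 110, 140,
                center_rest = sc + c(0, 0, -0.4),
                center_premove = sc + c(0, 0, -0.2),
                center_move_start = sc + c(0, 0, -0.2),
                center_move_end = sc + c(0, 0, -0.2) + c(0, 0, 0.84),
                spatial_sigma = 1.5, amp_rest = 0.6, amp_premove = 0.65,
                move_envelope_peak_frac = 0.48, move_envelope_gain = 1.1),
    source_spec("SHFO", 202, 298,
                center_rest = sc + c(0, -0.3, -0.8),
                center_premove = sc + c(0, -0.3, -0.6),
                center_move_start = sc + c(0, -0.3, -0.6),
                center_move_end = sc + c(0, -0.3, -0.6) + c(0, 0, -0.4),
                spatial_sigma = 1.5, amp_rest = 0.5, amp_premove = 0.55,
                move_envelope_peak_frac = 0.44, move_envelope_gain = 1.2,
                random_shift_mm = 0.4),
    source_spec("FHFO", 302, 390,
                center_rest = sc + c(0, -0.3, -0.8),
                spatial_sigma = 1.5, amp_rest = 0.45, amp_premove = 0.5,
                move_envelope_peak_frac = 0.43, move_envelope_gain = 1.1,
                random_shift_mm = 0.5)
  )
}

#' Synthetic-cohort configuration
#'
#' Defaults mirror the intraoperative study conditions: 2048 Hz raw
#' sampling, ~18 kept trials per hemisphere, 8 s intertrial interval,
#' cue-to-EMG-onset delay 0.43 +/- 0.18 s, movement duration
#' 1.54 +/- 0.59 s, ~93 s rest block, and an EMG burst peaking at 29% of
#' the movement.
#'
#' @param n_hemispheres cohort size (study cohort: 63).
#' @param n_trials cued movements per hemisphere (default 18).
#' @param fs_raw raw sampling rate, Hz (default 2048).
#' @param trial_gap_s intertrial interval, s (default 8).
#' @param cue_to_onset_s mean/SD of cue-to-movement-onset delay, s.
#' @param movement_dur_s mean/SD of movement duration, s.
#' @param rest_dur_s rest-block duration, s (default 93).
#' @param sources list of `source_spec` (default `default_sources()`).
#' @param stn_model STN geometry (default `stn_ellipsoid()`).
#' @param pink_noise_scale 1/f background noise SD relative to unit
#'   carriers.
#' @param line_noise_50hz_amp 50 Hz mains amplitude.
#' @param target_jitter_mm,entry_jitter lead trajectory jitter.
#' @param prop_scale_sd SD of the per-hemisphere propagation scale
#'   (multiplies every source's planted movement shift; mean 1).
#' @param emg_peak_frac planted EMG envelope peak fraction (default 0.29).
#' @param rng_seed master seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_hemispheres = 63, n_trials = 18, fs_raw = 2048,
                         trial_gap_s = 8, cue_to_onset_s = c(0.43, 0.18),
                         movement_dur_s = c(1.54, 0.59), rest_dur_s = 93,
                         sources = default_sources(), stn_model = stn_ellipsoid(),
                         pink_noise_scale = 0.6, line_noise_50hz_amp = 0.3,
                         target_jitter_mm = 1, entry_jitter = 0.12,
                         prop_scale_sd = 0.35, emg_peak_frac = 0.29,
                         rng_seed = 1L) {
  stopifnot(n_hemispheres >= 1, n_trials >= 1, fs_raw > 0, trial_gap_s > 0,
            rest_dur_s > 0, movement_dur_s[1] > 0)
  top <- max(vapply(sources, function(s) s$f_hi, numeric(1)))
  if (fs_raw < 2 * top)
    stopf("synth_config: fs_raw = %g below 2x top band edge (%g Hz)", fs_raw, top)
  structure(as.list(environment()), class = "synth_config")
}

## Raised-cosine bump on [0, 1] peaking at p: 0 at the edges, 1 at p,
## smooth on both flanks (possibly asymmetric).
raised_cosine_bump <- function(frac, p) {
  p <- min(max(p, 1e-6), 1 - 1e-6)
  out <- numeric(length(frac))
  lo <- frac >= 0 & frac <= p
  hi <- frac > p & frac <= 1
  out[lo] <- 0.5 - 0.5 * cos(pi * frac[lo] / p)
  out[hi] <- 0.5 + 0.5 * cos(pi * (frac[hi] - p) / (1 - p))
  out
}

## Unit-variance band-limited Gaussian noise carrier (zero-phase FIR
## band-pass of white noise). >= 95% of power lands inside [f_lo, f_hi].
band_carrier <- function(n, fs, f_lo, f_hi) {
  ny <- fs / 2
  ord <- max(256L, ceiling(6 * fs / max(f_lo, 1)))
  ord <- min(ord, floor(n / 4) * 2)
  b <- signal::fir1(ord, c(f_lo, min(f_hi, 0.99 * ny)) / ny, type = "pass")
  x <- signal::filtfilt(as.numeric(b), 1, rnorm(n))
  x / sd(x)
}

## 1/f ("pink") noise via FFT spectral shaping, unit variance.
## Computed at a highly composite length (fast FFT) and truncated.
pink_noise <- function(n, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)            # symmetric fold
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

gauss_gain <- function(pos, center, sigma) {
  d2 <- colSums((t(pos) - center)^2)
  exp(-d2 / (2 * sigma^2))
}

## Per-hemisphere planted movement shifts, one 3-vector per source: the
## source's directed shift scaled by an independent positive factor
## (mean 1, SD prop_scale_sd), plus an optional random-direction x-z
## component of magnitude random_shift_mm (also scaled). Band scales are
## independent across sources, so per-band propagation varies between
## hemispheres without cross-band coupling. RNG state: caller-seeded.
draw_hemi_shifts <- function(sources, prop_scale_sd) {
  out <- lapply(sources, function(s) {
    sc <- max(0.2, rnorm(1, 1, prop_scale_sd))
    sh <- sc * (s$center_move_end - s$center_move_start)
    if (s$random_shift_mm > 0) {
      th <- runif(1, 0, 2 * pi)
      sh <- sh + sc * s$random_shift_mm * c(cos(th), 0, sin(th))
    }
    sh
  })
  names(out) <- vapply(sources, function(s) s$band_name, "")
  out
}

#' Simulate one hemisphere recording
#'
#' Builds the full monopolar recording: per contact, the sum over sources
#' of spatial gain x movement-locked amplitude envelope x band-limited
#' carrier, plus 1/f noise and optional 50 Hz line noise; a signed
#' (pre-rectification) EMG channel with band-limited bursts; and the true
#' event table. Hotspot propagation is planted by interpolating each
#' source center from `center_move_start` to `center_move_end` across the
#' movement, scaled by the hemisphere's propagation factor.
#'
#' @param config `synth_config`.
#' @param geometry contact data.frame from [make_lead_geometry()].
#' @param seed integer seed.
#' @param hemisphere_id identifier string.
#' @param shifts optional named list (band -> 3-vector, mm) of planted
#'   movement shifts for this hemisphere; default: each source's
#'   `center_move_end - center_move_start`.
#' @return list with `recording` (class `lead_recording`: `hemisphere_id`,
#'   `fs`, `lfp` 8 x n, `emg`, `events`, `contacts`, `side`) and `truth`
#'   (planted per-trial events, envelope fractions, per-band shifts).
#' @export
simulate_recording <- function(config, geometry, seed, hemisphere_id = "hemi01",
                               shifts = NULL) {
  fs <- config$fs_raw
  with_seed(seed, {
    ## --- event schedule ---------------------------------------------------
    delays <- pmax(0.1, rnorm(config$n_trials, config$cue_to_onset_s[1],
                              config$cue_to_onset_s[2]))
    durs <- pmax(0.4, rnorm(config$n_trials, config$movement_dur_s[1],
                            config$movement_dur_s[2]))
    cues <- numeric(config$n_trials)
    t0 <- config$rest_dur_s + 5
    for (k in seq_len(config$n_trials)) {
      cues[k] <- t0
      t0 <- t0 + delays[k] + durs[k] + config$trial_gap_s
    }
    onsets <- cues + delays
    offsets <- onsets + durs
    total_s <- t0 + 4
    n <- ceiling(total_s * fs)
    tt <- (seq_len(n) - 1) / fs

    pos <- as.matrix(geometry[, c("x", "y", "z")])
    lfp <- matrix(0, nrow = 8, ncol = n)

    for (s in config$sources) {
      carrier <- band_carrier(n, fs, s$f_lo, s$f_hi)
      ## amplitude envelope over the whole recording
      amp <- rep(s$amp_rest, n)
      shift <- shifts[[s$band_name]] %||%
        (s$center_move_end - s$center_move_start)
      ## gain: piecewise-constant center outside movement
      g_rest <- gauss_gain(pos, s$center_rest, s$spatial_sigma)
      g_pre <- gauss_gain(pos, s$center_premove, s$spatial_sigma)
      gain <- matrix(rep(g_rest, n), nrow = 8)
      for (k in seq_len(config$n_trials)) {
        ipre <- which(tt >= cues[k] - 1.5 & tt < cues[k] - 0.2)
        amp[ipre] <- s$amp_premove
        gain[, ipre] <- g_pre
        ## desynchronizing sources start their dip before EMG onset
        ## (readiness-period suppression); the trough stays at
        ## move_envelope_peak_frac of the movement
        lead <- if (s$polarity < 0) 0.5 else 0
        imov <- which(tt >= onsets[k] - lead & tt <= offsets[k])
        if (length(imov) < 2) next
        u <- (tt[imov] - onsets[k] + lead) / (durs[k] + lead)
        up <- (s$move_envelope_peak_frac * durs[k] + lead) / (durs[k] + lead)
        amp[imov] <- pmax(0, s$amp_rest + s$polarity * s$move_envelope_gain *
                            raised_cosine_bump(u, up))
        frac <- pmax(0, (tt[imov] - onsets[k]) / durs[k])
        centers <- outer(rep(1, length(imov)), s$center_move_start) +
          outer(frac, shift)
        d2 <- (outer(centers[, 1], pos[, 1], `-`))^2 +
          (outer(centers[, 2], pos[, 2], `-`))^2 +
          (outer(centers[, 3], pos[, 3], `-`))^2
        gain[, imov] <- t(exp(-d2 / (2 * s$spatial_sigma^2)))
      }
      src <- amp * carrier
      lfp <- lfp + gain * matrix(rep(src, each = 8), nrow = 8)
    }
    for (c_i in 1:8) {
      lfp[c_i, ] <- lfp[c_i, ] + config$pink_noise_scale * pink_noise(n, fs)
      if (config$line_noise_50hz_amp > 0)
        lfp[c_i, ] <- lfp[c_i, ] + config$line_noise_50hz_amp *
          sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
    }

    ## --- EMG: signed band-limited bursts ----------------------------------
    emg_car <- band_carrier(n, fs, 30, min(350, 0.45 * fs))
    emg_env <- rep(0.08, n)             # baseline muscle tone
    for (k in seq_len(config$n_trials)) {
      imov <- which(tt >= onsets[k] & tt <= offsets[k])
      if (length(imov) < 2) next
      frac <- (tt[imov] - onsets[k]) / durs[k]
      emg_env[imov] <- 0.08 + raised_cosine_bump(frac, config$emg_peak_frac)
    }
    emg <- emg_env * emg_car

    events <- data.frame(cue_time = cues, emg_onset = onsets,
                         emg_offset = offsets, artifact = FALSE)
    rec <- structure(list(hemisphere_id = hemisphere_id, fs = fs,
                          lfp = 10 * lfp, emg = 10 * emg, events = events,
                          contacts = geometry, side = "right"),
                     class = "lead_recording")
    truth <- list(
      hemisphere_id = hemisphere_id,
      events = events,
      emg_peak_frac = config$emg_peak_frac,
      band_truth = lapply(config$sources, function(s) {
        sh <- shifts[[s$band_name]] %||%
          (s$center_move_end - s$center_move_start)
        list(band = s$band_name,
             center_rest = s$center_rest, center_premove = s$center_premove,
             center_move_start = s$center_move_start,
             center_move_end = s$center_move_start + sh,
             peak_frac = s$move_envelope_peak_frac, polarity = s$polarity,
             planted_shift = sh)
      })
    )
    names(truth$band_truth) <- vapply(config$sources, function(s) s$band_name, "")
    list(recording = rec, truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Per-hemisphere seeds are derived from the master seed, so hemispheres
#' are independent and the whole cohort is reproducible byte-for-byte.
#'
#' @param config `synth_config`.
#' @return list of class `synth_cohort`: `recordings`, `geometries`,
#'   `truth` (per hemisphere + cohort-level), `clinical` (from
#'   [simulate_clinical_scores()]), `config`.
#' @export
simulate_cohort <- function(config) {
  master <- config$rng_seed
  hemi_ids <- sprintf("hemi%02d", seq_len(config$n_hemispheres))
  shifts <- with_seed(derive_seed(master, 999983L),
                      lapply(seq_len(config$n_hemispheres), function(h)
                        draw_hemi_shifts(config$sources, config$prop_scale_sd)))
  out <- vector("list", config$n_hemispheres)
  for (h in seq_len(config$n_hemispheres)) {
    gseed <- derive_seed(master, 2L * h)
    geom <- make_lead_geometry(config$stn_model, gseed,
                               target_jitter_mm = config$target_jitter_mm,
                               entry_jitter = config$entry_jitter)
    out[[h]] <- simulate_recording(config, geom, derive_seed(master, 2L * h + 1L),
                                   hemisphere_id = hemi_ids[h],
                                   shifts = shifts[[h]])
  }
  truth <- lapply(out, `[[`, "truth")
  names(truth) <- hemi_ids
  clinical <- simulate_clinical_scores(truth, seed = derive_seed(master, 424243L))
  structure(list(recordings = setNames(lapply(out, `[[`, "recording"), hemi_ids),
                 geometries = setNames(lapply(out, function(o) o$recording$contacts), hemi_ids),
                 truth = truth, clinical = clinical, config = config),
            class = "synth_cohort")
}

#' Simulate clinical scores linked to planted propagation
#'
#' Percentage levodopa improvement is linear in the per-hemisphere planted
#' propagation magnitudes (Euclidean norm of each band's scaled movement
#' shift) plus Gaussian noise, clipped to `[0, 100]`; the MDS-UPDRS III
#' OFF score is generated on the 0-132 scale and ON derived from the
#' improvement. Default coefficients plant a negative dependence of
#' improvement on the propagation of the bands above 110 Hz (FG, SHFO,
#' FHFO) and none on HG.
#'
#' @param truth per-hemisphere ground-truth list (from [simulate_cohort()]).
#' @param coeffs named numeric, % improvement per mm of planted
#'   propagation for each band.
#' @param intercept improvement intercept, %.
#' @param noise_sd Gaussian noise SD on the improvement, %.
#' @param off_mean,off_sd OFF-score distribution (points).
#' @param seed integer seed.
#' @return data.frame of class `clinical_records`: `hemisphere_id`,
#'   `patient_id`, `updrs3_off`, `updrs3_on`, `pct_improvement`,
#'   `ledd_mg`, with the generating coefficients as attribute `coeffs`.
#' @export
simulate_clinical_scores <- function(truth,
                                     coeffs = c(HG = 0, FG = -20, SHFO = -19, FHFO = -34),
                                     intercept = 107, noise_sd = 8.5,
                                     off_mean = 39.4, off_sd = 11.4, seed = 1L) {
  nh <- length(truth)
  pm <- vapply(truth, function(tr) {
    vapply(names(coeffs), function(b) {
      bt <- tr$band_truth[[b]]
      if (is.null(bt)) 0 else sqrt(sum(bt$planted_shift^2))
    }, numeric(1))
  }, numeric(length(coeffs)))
  prop <- if (is.matrix(pm)) t(pm) else matrix(pm, ncol = 1)
  colnames(prop) <- names(coeffs)
  with_seed(seed, {
    imp <- intercept + as.numeric(prop %*% coeffs) + rnorm(nh, 0, noise_sd)
    imp <- pmin(100, pmax(0, imp))
    off <- pmin(132, pmax(5, rnorm(nh, off_mean, off_sd)))
    on <- pmax(0, off * (1 - imp / 100))
    ledd <- pmax(0, rnorm(nh, 1084.2, 563.4))
    res <- data.frame(hemisphere_id = names(truth),
                      patient_id = names(truth),
                      updrs3_off = off, updrs3_on = on,
                      pct_improvement = 100 * (off - on) / off,
                      ledd_mg = ledd, stringsAsFactors = FALSE)
    attr(res, "coeffs") <- coeffs
    class(res) <- c("clinical_records", "data.frame")
    res
  })
}

#' Simulate a cohort at the band-power level
#'
#' Generates per-contact, per-state band powers directly from the same
#' spatial-gain model as [simulate_recording()] (power proportional to
#' squared gain x squared state amplitude, with multiplicative log-normal
#' noise), skipping waveform synthesis. This is the generator used to
#' calibrate the spatial statistics (hotspot recovery, surrogate nulls)
#' at realistic cohort sizes and replicate counts; the signal-level path
#' exercises the identical downstream code on smaller cohorts.
#'
#' With `spatial_null = TRUE` powers are i.i.d. across contacts
#' (no spatial structure, contacts exchangeable): the null condition for
#' calibration of the surrogate propagation test.
#'
#' @param n_hemispheres cohort size.
#' @param sources list of `source_spec`.
#' @param stn_model STN geometry.
#' @param seed master seed.
#' @param noise_sdlog log-normal power noise (default 0.4).
#' @param move_bins movement percent grid (default `seq(0, 100, 5)`).
#' @param spatial_null if TRUE, ignore geometry in the power draw.
#' @param prop_scale_sd per-hemisphere propagation scale SD.
#' @return list of class `power_cohort`: per hemisphere `contacts` and
#'   `power[[band]]` = list(`rest`, `premove` 8-vectors, `move` 8 x bins
#'   matrix); attribute `truth` holds planted per-hemisphere shifts.
#' @export
simulate_power_cohort <- function(n_hemispheres, sources = default_sources(),
                                  stn_model = stn_ellipsoid(), seed = 1L,
                                  noise_sdlog = 0.4,
                                  move_bins = seq(0, 100, 5),
                                  spatial_null = FALSE, prop_scale_sd = 0.35) {
  all_shifts <- with_seed(derive_seed(seed, 999983L),
                          lapply(seq_len(n_hemispheres), function(h)
                            draw_hemi_shifts(sources, prop_scale_sd)))
  hemi_ids <- sprintf("hemi%02d", seq_len(n_hemispheres))
  hemis <- vector("list", n_hemispheres)
  truth <- vector("list", n_hemispheres)
  fracs <- move_bins / 100
  for (h in seq_len(n_hemispheres)) {
    geom <- make_lead_geometry(stn_model, derive_seed(seed, 2L * h))
    pos <- as.matrix(geom[, c("x", "y", "z")])
    pw <- list()
    btr <- list()
    with_seed(derive_seed(seed, 2L * h + 1L), {
      for (s in sources) {
        shift <- all_shifts[[h]][[s$band_name]]
        if (spatial_null) {
          base <- function(k) rep(1, 8)
          g_move <- matrix(1, 8, length(fracs))
        } else {
          g_move <- vapply(fracs, function(f)
            gauss_gain(pos, s$center_move_start + f * shift, s$spatial_sigma),
            numeric(8))
        }
        noise <- function() exp(rnorm(8, 0, noise_sdlog))
        mknoise_m <- function(nc) exp(matrix(rnorm(8 * nc, 0, noise_sdlog), 8, nc))
        amp_move <- s$amp_rest + s$polarity * s$move_envelope_gain *
          raised_cosine_bump(fracs, s$move_envelope_peak_frac)
        pw[[s$band_name]] <- list(
          rest = (if (spatial_null) rep(1, 8) else
            gauss_gain(pos, s$center_rest, s$spatial_sigma))^2 *
            s$amp_rest^2 * noise(),
          premove = (if (spatial_null) rep(1, 8) else
            gauss_gain(pos, s$center_premove, s$spatial_sigma))^2 *
            s$amp_premove^2 * noise(),
          move = g_move^2 * matrix(rep(pmax(amp_move, 0.05)^2, each = 8), 8) *
            mknoise_m(length(fracs))
        )
        btr[[s$band_name]] <- list(
          band = s$band_name, center_rest = s$center_rest,
          center_premove = s$center_premove,
          center_move_start = s$center_move_start,
          center_move_end = s$center_move_start + shift,
          planted_shift = shift, peak_frac = s$move_envelope_peak_frac,
          polarity = s$polarity)
      }
    })
    hemis[[h]] <- list(hemisphere_id = hemi_ids[h], contacts = geom, power = pw)
    truth[[h]] <- list(hemisphere_id = hemi_ids[h], band_truth = btr)
  }
  names(hemis) <- names(truth) <- hemi_ids
  structure(hemis, truth = truth, move_bins = move_bins, class = "power_cohort")
}
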