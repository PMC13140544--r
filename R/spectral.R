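.dpss_cache <- new.env(parent = emptyenv())

## Discrete prolate spheroidal (Slepian) tapers via the standard
## symmetric tridiagonal eigenproblem; columns are tapers with unit
## energy, ordered by concentration. Cached per (n, nw, k).
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "|")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_i <- 0:(n - 1)
  w <- nw / n
  diag_main <- ((n - 1 - 2 * t_i) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_i[-1] * (n - t_i[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {         # polarity convention: positive mean lobe
    if (sum(v[, j]) < 0 || (abs(sum(v[, j])) < 1e-8 && v[2, j] < 0))
      v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power estimate with DPSS tapers. The
#' time-half-bandwidth product is `window_s x half_bw_hz` and the taper
#' count is `max(1, floor(2 TW) - 1)`; with the low-range configuration
#' (400 ms, +/- 2 Hz) this floors at a single taper. The frequency grid
#' spacing is `1 / window_s` -- 2.5 Hz for the low range and 5 Hz for the
#' high range at 800 Hz. Total power is calibrated so that summing the
#' one-sided spectrum recovers the signal variance (Parseval).
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param range_cfg one of `spectral_config()$low` / `$high` (fields
#'   `f_lo`, `f_hi`, `window_s`, `step_s`, `half_bw_hz`).
#' @return list with `freq` (Hz), `time` (s, frame centers), `power`
#'   (freq x frames), `n_tapers`.
#' @export
multitaper_spectrogram <- function(x, fs, range_cfg) {
  nw_samp <- round(range_cfg$window_s * fs)
  if (length(x) < nw_samp)
    stopf("multitaper_spectrogram: signal (%d samples) shorter than window (%d)",
          length(x), nw_samp)
  step <- max(1L, round(range_cfg$step_s * fs))
  tw <- range_cfg$window_s * range_cfg$half_bw_hz
  k <- max(1L, floor(2 * tw) - 1L)
  tapers <- dpss_tapers(nw_samp, tw, k)
  starts <- seq(1L, length(x) - nw_samp + 1L, by = step)
  frames <- vapply(starts, function(s) x[s:(s + nw_samp - 1L)],
                   numeric(nw_samp))
  acc <- matrix(0, nw_samp, length(starts))
  for (j in seq_len(k)) {
    X <- stats::mvfft(frames * tapers[, j])
    acc <- acc + Mod(X)^2
  }
  p_full <- acc / (k * nw_samp)
  nf <- floor(nw_samp / 2) + 1L
  p <- p_full[seq_len(nf), , drop = FALSE]
  if (nf > 2) p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]  # one-sided doubling
  freq <- (seq_len(nf) - 1L) * fs / nw_samp
  sel <- freq >= range_cfg$f_lo & freq <= range_cfg$f_hi
  list(freq = freq[sel], time = (starts - 1L + (nw_samp - 1) / 2) / fs,
       power = p[sel, , drop = FALSE], n_tapers = k)
}

#' Baseline z-scored event-related synchronization
#'
#' Per frequency bin, z = (P - mu_base) / sigma_base with the baseline
#' moments pooled over the baseline frames of all kept trials (the
#' default pooling; the baseline is the (-3, -2) s pre-onset window).
#' Channels with a zero baseline SD at any frequency are flagged.
#'
#' @param power_trials list of per-trial power matrices (freq x frames,
#'   same frequency grid).
#' @param baseline_idx list of per-trial frame-index vectors marking
#'   baseline frames.
#' @return list with `z` (list of z matrices), `mu`, `sigma` (per-freq
#'   baseline moments), `flagged` (logical per freq).
#' @export
zscore_ers <- function(power_trials, baseline_idx) {
  stopifnot(length(power_trials) == length(baseline_idx))
  base <- do.call(cbind, Map(function(p, i) p[, i, drop = FALSE],
                             power_trials, baseline_idx))
  if (ncol(base) < 2) stopf("zscore_ers: no baseline frames")
  mu <- rowMeans(base)
  sigma <- apply(base, 1, sd)
  flagged <- sigma < 1e-14
  sigma[flagged] <- NA_real_
  z <- lapply(power_trials, function(p) (p - mu) / sigma)
  list(z = z, mu = mu, sigma = sigma, flagged = flagged)
}

## Average z rows into analysis bands. Returns band x frames.
band_average <- function(z, freq, bands) {
  out <- matrix(NA_real_, nrow(bands), ncol(z))
  for (b in seq_len(nrow(bands))) {
    sel <- freq >= bands$f_lo[b] & freq <= bands$f_hi[b]
    if (any(sel)) out[b, ] <- colMeans(z[sel, , drop = FALSE])
  }
  rownames(out) <- bands$band
  out
}

#' Normalize a frame series onto the percent-of-movement grid
#'
#' Linear interpolation of 10 ms frame values onto the inclusive 0-100%
#' grid in 5% steps (21 points), making trials of different durations
#' averageable.
#'
#' @param values numeric vector or matrix (series x frames).
#' @param frame_times frame times, s relative to movement onset.
#' @param duration movement duration, s.
#' @param grid percent grid (default `seq(0, 100, 5)`).
#' @return vector or matrix on the percent grid.
#' @export
normalize_movement_time <- function(values, frame_times, duration,
                                    grid = seq(0, 100, 5)) {
  if (duration <= 0) stopf("normalize_movement_time: nonpositive duration")
  frac <- frame_times / duration * 100
  if (sum(frac >= -1e-9 & frac <= 100 + 1e-9) < 2)
    stopf("normalize_movement_time: movement shorter than 2 frames")
  f <- function(v) approx(frac, v, xout = grid, rule = 2)$y
  if (is.matrix(values)) t(apply(values, 1, f)) else f(values)
}

## Rest interval of a recording: start of recording up to just before the
## first cue (with guard margins).
rest_interval <- function(events, margin = c(1, 4.5)) {
  c(margin[1], max(margin[1] + 1, min(events$cue_time) - margin[2]))
}

#' Compute the full ERS tensor for one hemisphere
#'
#' Runs the two multitaper ranges over every kept trial and contact,
#' pools the baseline across trials, z-scores, averages into bands, and
#' assembles the state-resolved views: movement on the 21-point percent
#' grid (per trial, then trial-averaged), pre-movement and rest in
#' 100 ms epochs, plus the trial-mean normalized rectified EMG on the
#' percent grid.
#'
#' @param pre output of [preprocess_recording()].
#' @param scfg a `spectral_config`.
#' @return object of class `ers_tensor`: list with `hemisphere_id`,
#'   `contacts`, `bands`, `move` (contact x band x 21, trial mean),
#'   `move_trials` (contact x band x 21 x trials), `premove_epochs`,
#'   `rest_epochs` (contact x band x epoch), `state` (contact x band x
#'   {rest, premove, move}), `emg_move` (21), `flagged`.
#' @export
compute_hemisphere_ers <- function(pre, scfg = spectral_config()) {
  rec <- pre$rec
  epochs <- pre$epochs
  bands <- scfg$bands
  nb <- nrow(bands)
  ntr <- length(epochs)
  grid_n <- length(scfg$move_grid)
  move_tr <- array(NA_real_, c(8, nb, grid_n, ntr))
  pre_win <- c(-1.5, -0.2)

  ## pre-movement epochs: 100 ms partitions of the pre-cue window
  pre_len <- pre_win[2] - pre_win[1]
  n_pre_ep <- floor(pre_len / scfg$state_epoch_s + 1e-9)
  pre_tr <- array(NA_real_, c(8, nb, n_pre_ep, ntr))
  flagged <- matrix(FALSE, 8, 2)

  ## rest block: continuous segment before the first cue, z-scored with
  ## the pooled trial-baseline moments
  ri_win <- rest_interval(pre$events)
  i0 <- max(1L, round(ri_win[1] * rec$fs)); i1 <- round(ri_win[2] * rec$fs)
  rest_ep <- NULL

  ranges <- list(low = scfg$low, high = scfg$high)
  for (ci in 1:8) {
    for (ri in seq_along(ranges)) {
      rg <- ranges[[ri]]
      specs <- lapply(epochs, function(e)
        multitaper_spectrogram(e$lfp[ci, ], rec$fs, rg))
      base_idx <- lapply(seq_len(ntr), function(i) {
        tt <- specs[[i]]$time + epochs[[i]]$time[1]
        which(tt >= -3 & tt <= -2)
      })
      zz <- zscore_ers(lapply(specs, `[[`, "power"), base_idx)
      if (any(zz$flagged)) flagged[ci, ri] <- TRUE
      ## rest view on the same z-reference
      sp_rest <- multitaper_spectrogram(rec$lfp[ci, i0:i1], rec$fs, rg)
      zr <- (sp_rest$power - zz$mu) / zz$sigma
      bzr <- band_average(zr, sp_rest$freq, bands)
      n_rep <- floor((max(sp_rest$time) - min(sp_rest$time)) / scfg$state_epoch_s)
      if (is.null(rest_ep)) rest_ep <- array(NA_real_, c(8, nb, n_rep))
      bsel_r <- which(bands$range == names(ranges)[ri])
      for (ep in seq_len(min(n_rep, dim(rest_ep)[3]))) {
        e0 <- min(sp_rest$time) + (ep - 1) * scfg$state_epoch_s
        sel <- sp_rest$time >= e0 & sp_rest$time < e0 + scfg$state_epoch_s
        if (any(sel)) rest_ep[ci, bsel_r, ep] <- rowMeans(bzr[bsel_r, sel, drop = FALSE])
      }
      for (i in seq_len(ntr)) {
        tt <- specs[[i]]$time + epochs[[i]]$time[1]
        bz <- band_average(zz$z[[i]], specs[[i]]$freq, bands)
        dur <- epochs[[i]]$movement_duration_s
        imov <- which(tt >= 0 & tt <= dur)
        if (length(imov) >= 2) {
          bsel <- which(bands$range == names(ranges)[ri])
          g <- normalize_movement_time(bz[bsel, imov, drop = FALSE], tt[imov], dur,
                                       scfg$move_grid)
          move_tr[ci, bsel, , i] <- g
          ## pre-movement epochs relative to the cue
          tcue <- tt - epochs[[i]]$cue_time
          for (ep in seq_len(n_pre_ep)) {
            e0 <- pre_win[1] + (ep - 1) * scfg$state_epoch_s
            sel <- tcue >= e0 & tcue < e0 + scfg$state_epoch_s
            if (any(sel))
              pre_tr[ci, bsel, ep, i] <- rowMeans(bz[bsel, sel, drop = FALSE])
          }
        }
      }
    }
  }
  move <- apply(move_tr, c(1, 2, 3), mean, na.rm = TRUE)
  premove_ep <- apply(pre_tr, c(1, 2, 3), mean, na.rm = TRUE)

  ## trial-mean normalized rectified EMG envelope on the percent grid
  ## (100 ms moving average extracts the envelope of the rectified signal)
  ksm <- max(1L, round(0.1 * rec$fs))
  emg_g <- rowMeans(vapply(epochs, function(e) {
    env <- as.numeric(stats::filter(e$emg, rep(1 / ksm, ksm), sides = 2))
    env[is.na(env)] <- 0
    dur <- e$movement_duration_s
    sel <- e$time >= 0 & e$time <= dur
    v <- normalize_movement_time(env[sel], e$time[sel], dur, scfg$move_grid)
    v / max(v)
  }, numeric(grid_n)))

  state <- array(NA_real_, c(8, nb, 3), dimnames = list(NULL, bands$band,
                                                        c("rest", "premove", "move")))
  state[, , "rest"] <- apply(rest_ep, c(1, 2), mean, na.rm = TRUE)
  state[, , "premove"] <- apply(premove_ep, c(1, 2), mean, na.rm = TRUE)
  state[, , "move"] <- apply(move, c(1, 2), mean, na.rm = TRUE)

  structure(list(hemisphere_id = rec$hemisphere_id, contacts = rec$contacts,
                 bands = bands, move = move, move_trials = move_tr,
                 premove_epochs = premove_ep, rest_epochs = rest_ep,
                 state = state, emg_move = emg_g, grid = scfg$move_grid,
                 n_trials = ntr, flagged = flagged),
            class = "ers_tensor")
}

#' Locate the peak (or trough) of a percent-grid curve
#'
#' Grid argmax with optional parabolic sub-bin refinement: a quadratic
#' vertex fit through the extremum and its neighbours. Refinement is
#' appropriate for low-noise (e.g. cohort-mean) curves; per-hemisphere
#' summaries use the plain argmax.
#'
#' @param curve numeric values on `grid`.
#' @param grid percent grid (default `seq(0, 100, 5)`).
#' @param what `"max"` or `"min"`.
#' @param refine parabolic refinement (default TRUE).
#' @return location in percent.
#' @export
grid_peak <- function(curve, grid = seq(0, 100, 5), what = c("max", "min"),
                      refine = TRUE) {
  what <- match.arg(what)
  v <- if (what == "min") -curve else curve
  i <- which.max(v)
  if (!refine || i == 1 || i == length(grid)) return(grid[i])
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < 1e-300) return(grid[i])
  delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  grid[i] + max(-1, min(1, delta)) * (grid[2] - grid[1])
}

#' Summarize movement-related synchronization per hemisphere
#'
#' For each band, the summary curve is taken at the inside-STN contact
#' with the highest movement-mean z. AUC is the plain sum of the 21 grid
#' values (z·bins); `peak_frac` is the grid argmax (%); the beta trough
#' (`erd_trough_frac`) is the grid argmin of the beta curve;
#' `emg_peak_frac` the argmax of the trial-mean normalized EMG;
#' `delta_ers_emg = peak_frac - emg_peak_frac` and
#' `delta_ers_erd = erd_trough_frac - peak_frac` (signed %).
#'
#' @param ers an `ers_tensor`.
#' @return data.frame of class `ers_summary`, one row per high-frequency
#'   band.
#' @export
summarize_ers <- function(ers) {
  grid <- ers$grid
  inside <- which(ers$contacts$inside_stn)
  if (length(inside) == 0) stopf("summarize_ers: no inside-STN contacts")
  emg_peak <- grid[which.max(ers$emg_move)]
  bands <- ers$bands
  bsel_beta <- which(bands$band == "beta")
  beta_curve <- NULL
  if (length(bsel_beta)) {
    ci <- inside[which.min(apply(ers$move[inside, bsel_beta, , drop = FALSE], 1, mean))]
    beta_curve <- ers$move[ci, bsel_beta, ]
  }
  trough <- if (!is.null(beta_curve)) grid[which.min(beta_curve)] else NA_real_
  hi <- which(bands$range == "high")
  out <- do.call(rbind, lapply(hi, function(b) {
    mm <- apply(ers$move[inside, b, , drop = FALSE], 1, mean)
    ci <- inside[which.max(mm)]
    curve <- ers$move[ci, b, ]
    pk <- grid[which.max(curve)]
    data.frame(hemisphere_id = ers$hemisphere_id, band = bands$band[b],
               contact_id = ers$contacts$contact_id[ci],
               auc_total = sum(curve), peak_frac = pk,
               erd_trough_frac = trough, emg_peak_frac = emg_peak,
               delta_ers_emg = pk - emg_peak,
               delta_ers_erd = trough - pk,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("ers_summary", "data.frame")
  out
}

#' Standardized cross-correlation of paired series
#'
#' Rows of `a` and `b` are paired units (trials or hemispheres) on the
#' percent grid. The normalized cross-correlation is computed per pair
#' and averaged; the summary score is the mean correlation within
#' `score_lags` bins of lag 0, standardized against a null built by
#' shuffling the unit assignment of `b` (`n_shuffles` permutations).
#' Sign convention: positive lag means the first series leads.
#'
#' @param a,b numeric matrices (units x L) or vectors (treated as one
#'   unit; the shuffle null then requires >= 2 units).
#' @param n_shuffles permutations (default 1000).
#' @param seed RNG seed.
#' @param score_lags half-width of the scoring window in lag bins
#'   (default 3).
#' @return object of class `xcorr_result`: `lags`, `trace` (mean paired
#'   cross-correlation), `score`, `z` (standardized score), `p`
#'   (two-tailed permutation p), `null_mean`, `null_sd`.
#' @export
crosscorr_standardized <- function(a, b, n_shuffles = 1000, seed = 1L,
                                   score_lags = 3) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  stopifnot(all(dim(a) == dim(b)))
  L <- ncol(a); n <- nrow(a)
  std <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))
    if (any(s < 1e-14)) stopf("crosscorr_standardized: constant series")
    (m - mu) / s
  }
  A <- std(a); B <- std(b)
  lags <- -(L - 1):(L - 1)
  ## full trace for matched pairs
  trace <- vapply(lags, function(l) {
    if (l >= 0) mean(rowSums(A[, 1:(L - l), drop = FALSE] *
                               B[, (1 + l):L, drop = FALSE]) / L)
    else mean(rowSums(A[, (1 - l):L, drop = FALSE] *
                        B[, 1:(L + l), drop = FALSE]) / L)
  }, numeric(1))
  ## pairwise score matrix over the scoring window
  sl <- -score_lags:score_lags
  PS <- matrix(0, n, n)
  for (l in sl) {
    M <- if (l >= 0) A[, 1:(L - l), drop = FALSE] %*% t(B[, (1 + l):L, drop = FALSE]) / L
    else A[, (1 - l):L, drop = FALSE] %*% t(B[, 1:(L + l), drop = FALSE]) / L
    PS <- PS + M / length(sl)
  }
  obs <- mean(diag(PS))
  null <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    pm <- sample.int(n)
    mean(PS[cbind(seq_len(n), pm)])
  }, numeric(1)))
  mu0 <- mean(null); sd0 <- sd(null)
  structure(list(lags = lags, trace = trace, score = obs,
                 z = if (sd0 > 0) (obs - mu0) / sd0 else NA_real_,
                 p = perm_p_two_tailed(obs, null),
                 null_mean = mu0, null_sd = sd0, n_shuffles = n_shuffles),
            class = "xcorr_result")
}
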