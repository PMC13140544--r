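test_that("multitaper frequency grids have the prescribed spacing", {
  scfg <- spectral_config()
  x <- rnorm(4000)
  lo <- multitaper_spectrogram(x, 800, scfg$low)
  hi <- multitaper_spectrogram(x, 800, scfg$high)
  expect_equal(unique(diff(lo$freq)), 2.5, tolerance = 1e-12)
  expect_equal(unique(diff(hi$freq)), 5, tolerance = 1e-12)
  ## the single-taper floor applies to the low range, 3 tapers to the high
  expect_equal(lo$n_tapers, 1)
  expect_equal(hi$n_tapers, 3)
  ## every band contains at least two grid frequencies
  for (b in seq_len(nrow(scfg$bands))) {
    g <- if (scfg$bands$range[b] == "low") lo$freq else hi$freq
    expect_gte(sum(g >= scfg$bands$f_lo[b] & g <= scfg$bands$f_hi[b]), 2)
  }
})

test_that("multitaper power localizes tones and matches a periodogram oracle", {
  scfg <- spectral_config()
  tt <- (0:6399) / 800
  x <- sin(2 * pi * 130 * tt)
  sp <- multitaper_spectrogram(x, 800, scfg$high)
  pk <- sp$freq[which.max(rowMeans(sp$power))]
  expect_lte(abs(pk - 130), 10)
  ## total power ~ signal variance (Parseval), via a full-band config
  set.seed(2)
  w <- rnorm(8000)
  full <- list(f_lo = 0, f_hi = 400, window_s = 0.2, step_s = 0.01,
               half_bw_hz = 10)
  spf <- multitaper_spectrogram(w, 800, full)
  expect_lt(abs(sum(rowMeans(spf$power)) / var(w) - 1), 0.05)
  ## zero in, zero out
  expect_equal(max(multitaper_spectrogram(rep(0, 1000), 800, scfg$high)$power), 0)
  expect_error(multitaper_spectrogram(rnorm(100), 800, scfg$low), "shorter")
})

test_that("DPSS tapers are orthonormal and band-concentrated", {
  v <- dpss_tapers(160, 2, 3)
  expect_equal(t(v) %*% v, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  ## leading taper concentrates its spectrum within +/- W
  V <- abs(fft(c(v[, 1], rep(0, 1440))))^2
  f <- seq(0, 1, length.out = 1601)[1:800]   # cycles/sample
  inb <- sum(V[1:800][f <= 2 / 160]) / sum(V[1:800])
  expect_gt(inb, 0.99)
})

test_that("baseline z-scoring self-normalizes and flags constant channels", {
  set.seed(3)
  trials <- lapply(1:15, function(i) matrix(rexp(30 * 40), 30))
  bidx <- lapply(1:15, function(i) 1:15)
  z <- zscore_ers(trials, bidx)
  base_z <- do.call(cbind, Map(function(m, i) m[, i], z$z, bidx))
  expect_lt(abs(mean(base_z)), 0.05)
  expect_lt(abs(sd(base_z) - 1), 0.05)
  ## constant signal is flagged
  const <- lapply(1:3, function(i) matrix(1, 5, 20))
  zc <- zscore_ers(const, lapply(1:3, function(i) 1:10))
  expect_true(all(zc$flagged))
})

test_that("movement-time normalization is duration-invariant", {
  ## same fractional peak, different durations -> identical grid curves
  mk <- function(dur) {
    tt <- seq(0, dur, by = 0.01)
    list(v = raised_cosine_bump(tt / dur, 0.45), t = tt)
  }
  a <- mk(1); b <- mk(2)
  ga <- normalize_movement_time(a$v, a$t, 1)
  gb <- normalize_movement_time(b$v, b$t, 2)
  expect_equal(ga, gb, tolerance = 1e-6)
  expect_equal(seq(0, 100, 5)[which.max(ga)], 45)
  ## constant series stays constant; short movements error
  expect_equal(normalize_movement_time(rep(2, 50), seq(0, 1, length.out = 50), 1),
               rep(2, 21))
  expect_error(normalize_movement_time(1:3, c(0, 0.01, 0.02), 0), "duration")
})

test_that("ERS sign tracks planted amplitude changes by band", {
  ## amplitude step x2 inside one band only -> positive z there only
  set.seed(8)
  fs <- 800
  scfg <- spectral_config()
  n_b <- fs * 3
  n_m <- fs * 2
  x <- c(band_carrier(n_b, fs, 60, 90), 2 * band_carrier(n_m, fs, 60, 90)) +
    0.3 * rnorm(n_b + n_m)
  sp <- multitaper_spectrogram(x, fs, scfg$high)
  bidx <- which(sp$time <= 2.5)
  z <- zscore_ers(list(sp$power), list(bidx))
  bz <- band_average(z$z[[1]], sp$freq, stn_bands())
  late <- sp$time > 3.2
  expect_gt(mean(bz["HG", late]), 1)
  expect_lt(abs(mean(bz["FG", late])), 1.2)
  expect_lt(abs(mean(bz["FHFO", late])), 1.2)
})

test_that("cross-correlation conventions, bounds and degenerate inputs", {
  set.seed(9)
  a <- matrix(rnorm(15 * 21), 15)
  r <- crosscorr_standardized(a, a, n_shuffles = 200, seed = 1)
  expect_equal(max(r$trace), r$trace[r$lags == 0])
  expect_equal(r$trace[r$lags == 0], 1, tolerance = 1e-12)
  expect_true(all(abs(r$trace) <= 1 + 1e-12))
  expect_length(r$trace, 2 * 21 - 1)
  ## b = a delayed by 2 bins -> peak at +2 (first series leads)
  b <- cbind(matrix(rnorm(15 * 2), 15), a[, 1:19])
  r2 <- crosscorr_standardized(a, b, n_shuffles = 200, seed = 1)
  expect_equal(r2$lags[which.max(r2$trace)], 2)
  expect_error(crosscorr_standardized(matrix(1, 3, 21), a[1:3, ]), "constant")
})

test_that("standardized cross-correlation score is calibrated under independence", {
  set.seed(10)
  runs <- 300
  rej <- logical(runs)
  zs <- numeric(runs)
  for (i in seq_len(runs)) {
    a <- matrix(rnorm(12 * 21), 12)
    b <- matrix(rnorm(12 * 21), 12)
    r <- crosscorr_standardized(a, b, n_shuffles = 99, seed = i)
    rej[i] <- r$p <= 0.05
    zs[i] <- r$z
  }
  expect_lt(abs(mean(rej) - 0.05), 0.035)
  expect_lt(abs(mean(zs)), 0.15)
  expect_lt(abs(sd(zs) - 1), 0.25)
})

test_that("ERS summary AUC is the plain grid sum", {
  f <- fixture_recording(seed = 43, n_trials = 3, rest_s = 12)
  ers <- list(hemisphere_id = "h", contacts = f$geom, bands = stn_bands(),
              move = array(1, c(8, 5, 21)), grid = seq(0, 100, 5),
              emg_move = raised_cosine_bump(seq(0, 1, length.out = 21), 0.29))
  ers$contacts$inside_stn <- rep(TRUE, 8)
  s <- summarize_ers(structure(ers, class = "ers_tensor"))
  expect_equal(s$auc_total, rep(21, 4))   # constant z = 1 over 21 points
  expect_equal(s$emg_peak_frac, rep(30, 4))
})
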