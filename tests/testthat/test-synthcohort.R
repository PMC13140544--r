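test_that("lead geometry respects the Cartesia layout and the inclusion rule", {
  m <- fixture_stn()
  g <- make_lead_geometry(m, 42)
  expect_equal(nrow(g), 8)
  expect_equal(g$contact_id, 0:7)
  expect_equal(g$is_ring, c(TRUE, rep(FALSE, 6), TRUE))
  ## 2 mm center-to-center level spacing along the trajectory
  lvl <- rbind(as.numeric(g[1, c("x", "y", "z")]),
               colMeans(g[2:4, c("x", "y", "z")]),
               colMeans(g[5:7, c("x", "y", "z")]),
               as.numeric(g[8, c("x", "y", "z")]))
  d <- sqrt(rowSums(diff(lvl)^2))
  expect_equal(d, rep(2, 3), tolerance = 1e-9)
  ## segments sit 0.66 mm off the level centroid
  for (lv in list(2:4, 5:7)) {
    cen <- colMeans(g[lv, c("x", "y", "z")])
    off <- sqrt(rowSums(sweep(as.matrix(g[lv, c("x", "y", "z")]), 2, cen)^2))
    expect_equal(unname(off), rep(0.66, 3), tolerance = 1e-9)
  }
  expect_gte(sum(g$inside_stn), 2)
})

test_that("lead geometry is deterministic and rejection sampling always satisfies the inclusion rule", {
  m <- fixture_stn()
  expect_identical(make_lead_geometry(m, 7), make_lead_geometry(m, 7))
  ## brute-force check of the rejection-sampling contract
  frac_ok <- mean(vapply(1:300, function(s)
    sum(make_lead_geometry(m, s)$inside_stn) >= 2, logical(1)))
  expect_equal(frac_ok, 1)
})

test_that("a trajectory through a far-away STN fails after bounded retries", {
  ## shrink the model so that jittered trajectories essentially never hit it
  tiny <- stn_ellipsoid(semi_axes = c(1e-4, 1e-4, 1e-4))
  expect_error(make_lead_geometry(tiny, 1, target_jitter_mm = 30, max_retries = 20),
               "retries")
})

test_that("spatial gain is 1 at the source center and strictly decreasing with distance", {
  pos <- rbind(c(12, -13, -7), c(12, -13, -6), c(12, -13, -4), c(12, -10.5, -7))
  g <- gauss_gain(pos, c(12, -13, -7), 1.5)
  expect_equal(g[1], 1)
  d <- sqrt(colSums((t(pos) - c(12, -13, -7))^2))
  expect_true(all(diff(g[order(d)]) < 0))
})

test_that("band-limited carriers concentrate >= 95% of power in band", {
  set.seed(3)
  fs <- 800
  for (b in list(c(60, 90), c(110, 140), c(202, 298), c(302, 390))) {
    x <- band_carrier(fs * 30, fs, b[1], b[2])
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0, plot = FALSE,
                            detrend = FALSE)
    inband <- sp$freq >= b[1] - 2 & sp$freq <= b[2] + 2
    expect_gte(sum(sp$spec[inband]) / sum(sp$spec), 0.95)
  }
})

test_that("raised-cosine envelopes peak exactly at the requested fraction", {
  fr <- seq(0, 1, by = 1e-3)
  for (p in c(0.14, 0.29, 0.44, 0.48)) {
    b <- raised_cosine_bump(fr, p)
    expect_equal(fr[which.max(b)], p, tolerance = 2e-3)
    expect_equal(b[1], 0, tolerance = 1e-6)
    expect_equal(b[length(b)], 0, tolerance = 1e-6)
    expect_equal(max(b), 1, tolerance = 1e-9)
  }
})

test_that("simulate_recording is deterministic and respects the event invariants", {
  f1 <- fixture_recording(seed = 11, n_trials = 5, rest_s = 15)
  f2 <- fixture_recording(seed = 11, n_trials = 5, rest_s = 15)
  expect_identical(f1$sim$recording$lfp, f2$sim$recording$lfp)
  ev <- f1$sim$recording$events
  expect_true(all(ev$cue_time < ev$emg_onset))
  expect_true(all(ev$emg_onset < ev$emg_offset))
  expect_true(!is.unsorted(ev$cue_time))
})

test_that("cohort movement durations match the configured distribution", {
  cfg <- synth_config(n_hemispheres = 40, n_trials = 18, fs_raw = 800,
                      rng_seed = 5)
  durs <- unlist(lapply(1:40, function(h) {
    with_seed(derive_seed(5, 2L * h + 1L), {
      pmax(0.4, rnorm(cfg$n_trials, cfg$movement_dur_s[1], cfg$movement_dur_s[2]))
    })
  }))
  se <- cfg$movement_dur_s[2] / sqrt(length(durs))
  expect_lt(abs(mean(durs) - cfg$movement_dur_s[1]), 3 * se + 0.02)
})

test_that("clinical scores recompute and respond to planted coefficients", {
  pc <- simulate_power_cohort(30, seed = 9)
  truth <- attr(pc, "truth")
  cl <- simulate_clinical_scores(truth, seed = 3)
  expect_equal(cl$pct_improvement,
               100 * (cl$updrs3_off - cl$updrs3_on) / cl$updrs3_off,
               tolerance = 1e-9)
  expect_true(all(cl$updrs3_on <= cl$updrs3_off + 1e-9))
  ## zero coefficients -> no association with planted propagation
  cl0 <- simulate_clinical_scores(truth, coeffs = c(FG = 0), intercept = 50,
                                  noise_sd = 10, seed = 4)
  prop <- vapply(truth, function(tr) sqrt(sum(tr$band_truth$FG$planted_shift^2)),
                 numeric(1))
  expect_lt(abs(cor(prop, cl0$pct_improvement, method = "spearman")), 0.45)
  ## noiseless single negative coefficient -> exact monotone map
  cl1 <- simulate_clinical_scores(truth, coeffs = c(FG = -20), intercept = 80,
                                  noise_sd = 0, seed = 5)
  expect_equal(cor(prop, cl1$pct_improvement, method = "spearman"), -1)
})

test_that("null power cohorts have no spatial structure; planted cohorts do", {
  pc <- simulate_power_cohort(12, seed = 21, spatial_null = TRUE)
  ## under the null the selected max contact is uniform over inside contacts
  ids <- unlist(lapply(pc, function(h)
    select_max_contact(h$power$HG$move[, 11], h$contacts)$contact_id))
  expect_gte(length(unique(ids)), 3)
  pc2 <- simulate_power_cohort(12, seed = 21)
  expect_identical(names(pc2[[1]]$power),
                   c("beta", "HG", "FG", "SHFO", "FHFO"))
  expect_identical(dim(pc2[[1]]$power$HG$move), c(8L, 21L))
})
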