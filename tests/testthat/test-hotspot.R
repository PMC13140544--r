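test_that("ellipsoid containment matches the analytic oracle on random points", {
  m <- fixture_stn()
  set.seed(4)
  pts <- sweep(matrix(rnorm(3e4, sd = 5), ncol = 3), 2, m$center, `+`)
  cl <- stn_contains(m, pts)
  r2 <- rowSums(sweep(sweep(pts, 2, m$center), 2, m$semi_axes, `/`)^2)
  expect_identical(cl$inside, unname(r2 <= 1))
  ## centroid in, far point out
  expect_true(stn_contains(m, matrix(m$center, 1))$inside)
  expect_false(stn_contains(m, matrix(m$center + 50, 1))$inside)
})

test_that("mesh ray-casting containment agrees with the analytic ellipsoid", {
  m <- fixture_stn()
  mesh <- stn_mesh(list(motor = ellipsoid_mesh(m, 32, 64)))
  set.seed(5)
  pts <- sweep(matrix(rnorm(1500, sd = 4), ncol = 3), 2, m$center, `+`)
  r <- sqrt(rowSums(sweep(sweep(pts, 2, m$center), 2, m$semi_axes, `/`)^2))
  keep <- abs(r - 1) > 0.05          # skip the faceting boundary layer
  cl <- stn_contains(mesh, pts[keep, ])
  expect_identical(cl$inside, unname(r[keep] < 1))
})

test_that("select_max_contact picks the maximal inside contact with documented tie-break", {
  f <- fixture_recording(seed = 19, n_trials = 3, rest_s = 12)
  ct <- f$geom
  p <- rep(1, 8); p[5] <- 9
  expect_equal(select_max_contact(p, ct)$contact_id, 4)
  ## monotone transform invariance
  expect_equal(select_max_contact(exp(p), ct)$contact_id, 4)
  ## uniform powers: lowest inside contact_id
  u <- rep(2, 8)
  expect_equal(select_max_contact(u, ct)$contact_id,
               min(ct$contact_id[ct$inside_stn]))
  ct2 <- ct; ct2$inside_stn <- FALSE
  expect_error(select_max_contact(p, ct2), "inside")
})

test_that("weighted KDE peak matches the brute-force mixture oracle", {
  ## two-point instance on the z axis
  xyz <- rbind(c(0, 0, 0), c(0, 0, 4))
  hs <- weighted_kde_hotspot(xyz, c(2, 1))
  oracle <- brute_force_kde_peak(c(0, 4), c(2, 1), rep(hs$bw[3], 2))
  expect_lt(abs(hs$coord[3] - oracle), 1e-2)
  ## 5-point instances, random weights, all axes
  set.seed(8)
  for (rep_i in 1:5) {
    xyz <- matrix(rnorm(15, sd = 1.5), ncol = 3)
    w <- runif(5, 0.2, 1)
    hs <- weighted_kde_hotspot(xyz, w)
    for (a in 1:3) {
      oracle <- brute_force_kde_peak(xyz[, a], w, rep(hs$bw[a], 5))
      expect_lt(abs(hs$coord[a] - oracle), 1e-2)
    }
  }
})

test_that("KDE hotspot honors degenerate inputs and containment invariant", {
  ## all weight on one point -> that point
  xyz <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  hs <- weighted_kde_hotspot(xyz, c(1, 0, 0))
  expect_equal(unname(hs$coord), c(1, 2, 3), tolerance = 0.051)
  ## single unique coordinate returned directly
  one <- weighted_kde_hotspot(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 1))
  expect_equal(unname(one$coord), c(1, 1, 1))
  expect_error(weighted_kde_hotspot(xyz, c(0, 0, 0)), "zero")
  expect_error(weighted_kde_hotspot(xyz, c(-1, 1, 1)), "negative")
  ## peak containment within the coordinate range, every axis
  set.seed(9)
  for (i in 1:20) {
    xyz <- matrix(rnorm(24, sd = 2), ncol = 3)
    w <- runif(8)
    hs <- weighted_kde_hotspot(xyz, w)
    for (a in 1:3) {
      expect_gte(hs$coord[a], min(xyz[, a]) - 0.051)
      expect_lte(hs$coord[a], max(xyz[, a]) + 0.051)
    }
    ## per-axis densities integrate to 1
    for (ax in hs$axes)
      expect_equal(sum(ax$density) * diff(ax$grid[1:2]), 1, tolerance = 1e-6)
  }
})

test_that("joint KDE mode agrees with per-axis mode for separable data", {
  set.seed(10)
  xyz <- cbind(rnorm(12, 0, 1), rnorm(12, 5, 1), rnorm(12, -3, 1))
  w <- runif(12, 0.5, 1)
  h1 <- weighted_kde_hotspot(xyz, w)
  h2 <- weighted_kde_hotspot(xyz, w, joint = TRUE)
  expect_equal(unname(h1$coord), unname(h2$coord), tolerance = 0.3)
})

test_that("propagation deltas and Euclidean distance obey their invariants", {
  mk <- function(coord) structure(list(coord = coord), class = "hotspot")
  ref <- mk(c(12, -13, -7))
  pr <- propagation(list(mk(c(12, -13, -7)), mk(c(12.3, -12.6, -7)),
                         mk(c(12, -13, -5.82))), ref)
  expect_equal(pr$euclid[1], 0)
  expect_equal(pr$euclid[2], 0.5)           # 3-4-5 triangle
  expect_equal(pr$dz[3], 1.18)              # superior shift
  expect_true(all(pr$euclid + 1e-12 >= pmax(abs(pr$dx), abs(pr$dy), abs(pr$dz))))
})

test_that("volatility matches the exchangeability oracle and edge cases", {
  f <- fixture_recording(seed = 23, n_trials = 3, rest_s = 12)
  ct <- f$geom
  ct$inside_stn <- rep(TRUE, 8)
  ## constant argmax -> 0
  p <- matrix(1, 8, 10); p[3, ] <- 5
  expect_equal(volatility(p, ct), 0)
  ## alternating argmax -> 100
  p2 <- matrix(0, 8, 10); p2[1, c(TRUE, FALSE)] <- 1; p2[2, c(FALSE, TRUE)] <- 1
  expect_equal(volatility(p2, ct), 100)
  ## iid continuous powers over 8 contacts -> 100 * (1 - 1/8) = 87.5
  set.seed(11)
  v <- volatility(matrix(runif(8 * 10001), 8), ct)
  expect_lt(abs(v - 87.5), 2)
  ## strictly monotone transform invariance
  p3 <- matrix(runif(8 * 50), 8)
  expect_equal(volatility(p3, ct), volatility(exp(3 * p3), ct))
  expect_error(volatility(p3[, 1, drop = FALSE], ct), "2 bins")
})

test_that("per-hemisphere propagation recovers direct centroid jumps", {
  f <- fixture_recording(seed = 29, n_trials = 3, rest_s = 12)
  h <- list(hemisphere_id = "h", contacts = f$geom,
            power = list(HG = list(
              rest = c(1, rep(0, 7)), premove = c(1, rep(0, 7)),
              move = matrix(c(0, 1, rep(0, 6)), 8, 21))))
  h$contacts$inside_stn <- rep(TRUE, 8)
  d <- per_hemisphere_propagation(h, "HG", "premove", "move")
  expect_equal(unname(d["euclid"]),
               sqrt(sum((f$geom[2, c("x", "y", "z")] - f$geom[1, c("x", "y", "z")])^2)),
               tolerance = 1e-9)
  ## identical patterns -> zero
  h2 <- h
  h2$power$HG$move <- matrix(rep(c(1, rep(0, 7)), 21), 8)
  expect_equal(unname(per_hemisphere_propagation(h2, "HG")["euclid"]), 0)
})

test_that("magnitude-propagation ratio normalizes against cohort means", {
  mag <- data.frame(hemisphere_id = rep(c("a", "b"), each = 2),
                    band = rep(c("HG", "FG"), 2), auc = c(10, 10, 10, 10))
  pr <- data.frame(hemisphere_id = rep(c("a", "b"), each = 2),
                   band = rep(c("HG", "FG"), 2), propagation = c(1, 1, 1, 1))
  r <- magnitude_propagation_ratio(mag, pr)
  expect_true(all(abs(r$table$ratio - 1) < 1e-12))
  mag2 <- mag; mag2$auc <- c(20, 10, 20, 10)   # HG doubled vs mean of its own...
  r2 <- magnitude_propagation_ratio(mag2, pr)
  hg <- r2$table$ratio[r2$table$band == "HG"]
  fg <- r2$table$ratio[r2$table$band == "FG"]
  expect_true(all(hg > fg))
})

test_that("surrogate test is deterministic and bounds empirical p at extremes", {
  pc <- simulate_power_cohort(10, seed = 31)
  tc <- hotspot_timecourse(pc, "HG")
  s1 <- surrogate_test(pc, "HG", reference = tc$state$premove, bins = "state",
                       n = 120, seed = 5)
  s2 <- surrogate_test(pc, "HG", reference = tc$state$premove, bins = "state",
                       n = 120, seed = 5)
  expect_identical(s1$table$crit_lo, s2$table$crit_lo)
  expect_identical(s1$table$p, s2$table$p)
  expect_true(all(s1$table$p >= 1 / 121))
  expect_true(all(s1$table$crit_lo <= s1$table$crit_hi))
  expect_warning(surrogate_test(pc, "HG", reference = tc$state$premove,
                                bins = "state", n = 50, seed = 1), "unstable")
})

test_that("planted hotspot drift yields a monotone recovered z-trajectory", {
  pc <- simulate_power_cohort(40, seed = 37, noise_sdlog = 0.25,
                              prop_scale_sd = 0)
  tc <- hotspot_timecourse(pc, "HG")
  zs <- vapply(tc$move_bins, function(h) h$coord[3], numeric(1))
  ## drift is planted along +z: late bins sit above early bins
  expect_gt(mean(zs[15:21]), mean(zs[1:7]))
  ## rest vs movement-end states differ along the planted axis
  expect_gt(tc$move_bins[[21]]$coord[3] - tc$state$rest$coord[3], 0.4)
})
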