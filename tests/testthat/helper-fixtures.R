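## Shared fixtures, all generated in code.

fixture_stn <- function() stn_ellipsoid()

## Small signal-level cohort at the analysis rate (skips decimation cost;
## the decimation path has its own tests).
fixture_recording <- function(seed = 7, n_trials = 8, fs = 800, rest_s = 25,
                              sources = default_sources(), shifts = NULL) {
  cfg <- synth_config(n_hemispheres = 1, n_trials = n_trials, fs_raw = fs,
                      rest_dur_s = rest_s, sources = sources, rng_seed = seed)
  geom <- make_lead_geometry(cfg$stn_model, derive_seed(seed, 1L))
  sim <- simulate_recording(cfg, geom, derive_seed(seed, 2L), shifts = shifts)
  list(cfg = cfg, geom = geom, sim = sim)
}

## Deterministic two-point KDE oracle by brute-force grid search of the
## explicit Gaussian mixture at 1e-3 mm resolution.
brute_force_kde_peak <- function(x, w, bw, step = 1e-3) {
  w <- w / sum(w)
  g <- seq(min(x) - 3 * max(bw), max(x) + 3 * max(bw), by = step)
  d <- rep(0, length(g))
  for (i in seq_along(x)) d <- d + w[i] * stats::dnorm(g, x[i], bw)
  g[which.max(d)]
}
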