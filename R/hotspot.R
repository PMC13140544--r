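#' Classify contacts against an STN model
#'
#' Adds/overwrites `inside_stn` and `subregion` via the model's
#' containment test (analytic for ellipsoids, ray-casting for meshes).
#'
#' @param contacts contact data.frame with x, y, z.
#' @param stn_model an `stn_model`.
#' @return the contact data.frame with `inside_stn`, `subregion` set.
#' @export
classify_contacts <- function(contacts, stn_model) {
  cls <- stn_contains(stn_model, as.matrix(contacts[, c("x", "y", "z")]))
  contacts$inside_stn <- cls$inside
  contacts$subregion <- cls$subregion
  contacts
}

#' Select the maximal-power inside-STN contact
#'
#' Argmax of power over inside-STN contacts; ties are broken by the
#' lowest contact_id. Invariant under strictly monotone transforms of
#' power.
#'
#' @param power numeric length-8 power vector (contact order).
#' @param contacts contact data.frame.
#' @return list(`contact_id`, `row` index, `power`).
#' @export
select_max_contact <- function(power, contacts) {
  inside <- which(contacts$inside_stn)
  if (length(inside) == 0) stopf("select_max_contact: no inside-STN contacts")
  o <- inside[order(contacts$contact_id[inside])]
  r <- o[which.max(power[o])]     # which.max: first maximum = lowest id
  list(contact_id = contacts$contact_id[r], row = r, power = power[r])
}

## Weighted Silverman bandwidth, floored.
silverman_bw <- function(x, w, floor_mm = 0.3) {
  s <- weighted_sd(x, w)
  iq <- diff(weighted_quantile(x, w, c(0.25, 0.75))) / 1.34
  spread <- if (iq > 0) min(s, iq) else s
  n_eff <- effective_n(w)
  max(floor_mm, 0.9 * spread * n_eff^(-1 / 5))
}

#' Power-weighted KDE hotspot
#'
#' Per axis, a weighted Gaussian kernel density over the selected
#' contacts' coordinates (weights = state-normalized band power), with a
#' per-axis Silverman bandwidth floored at `bw_floor` mm. The hotspot
#' coordinate is the density argmax on a `grid_step` mm grid spanning the
#' data range +/- 3 bandwidths. A configurable joint (3-D product-kernel)
#' mode returns the joint-density argmax instead.
#'
#' @param xyz n x 3 coordinate matrix, mm.
#' @param weights nonnegative weights, not all zero.
#' @param bw_floor bandwidth floor, mm (default 0.3).
#' @param grid_step grid resolution, mm (default 0.05).
#' @param joint use the 3-D joint mode (default FALSE; per-axis).
#' @return object of class `hotspot`: `coord` (x, y, z), `axes` (per-axis
#'   grid + density, density integrating to 1), `bw`, `n_points`.
#' @export
weighted_kde_hotspot <- function(xyz, weights, bw_floor = 0.3, grid_step = 0.05,
                                 joint = FALSE) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (any(weights < 0)) stopf("weighted_kde_hotspot: negative weights")
  if (sum(weights) <= 0) stopf("weighted_kde_hotspot: all weights zero")
  w <- weights / sum(weights)
  if (nrow(unique(round(xyz, 9))) == 1) {
    return(structure(list(coord = xyz[1, ], axes = NULL,
                          bw = rep(NA_real_, 3), n_points = nrow(xyz)),
                     class = "hotspot"))
  }
  bw <- vapply(1:3, function(a) silverman_bw(xyz[, a], w, bw_floor), numeric(1))
  grids <- lapply(1:3, function(a) {
    r <- range(xyz[, a])
    seq(r[1] - 3 * bw[a], r[2] + 3 * bw[a], by = grid_step)
  })
  dens1 <- function(a) {
    g <- grids[[a]]
    d <- colSums(w * exp(-0.5 * outer(xyz[, a], g, `-`)^2 / bw[a]^2)) /
      (bw[a] * sqrt(2 * pi))
    d
  }
  dens <- lapply(1:3, dens1)
  ## sub-grid refinement: parabolic vertex through the argmax and its
  ## neighbours (keeps the peak accurate well below the grid step)
  refine <- function(g, d) {
    i <- which.max(d)
    if (i == 1 || i == length(g)) return(g[i])
    denom <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (abs(denom) < 1e-300) return(g[i])
    delta <- 0.5 * (d[i - 1] - d[i + 1]) / denom
    g[i] + max(-1, min(1, delta)) * (g[2] - g[1])
  }
  if (!joint) {
    coord <- vapply(1:3, function(a) refine(grids[[a]], dens[[a]]), numeric(1))
  } else {
    kx <- exp(-0.5 * outer(grids[[1]], xyz[, 1], `-`)^2 / bw[1]^2)
    ky <- exp(-0.5 * outer(grids[[2]], xyz[, 2], `-`)^2 / bw[2]^2)
    kz <- exp(-0.5 * outer(grids[[3]], xyz[, 3], `-`)^2 / bw[3]^2)
    best <- c(-Inf, NA, NA, NA)
    for (i in seq_len(nrow(xyz))) {
      if (i == 1) D <- array(0, c(length(grids[[1]]), length(grids[[2]]),
                                  length(grids[[3]])))
      D <- D + w[i] * (kx[, i] %o% ky[, i] %o% kz[, i])
    }
    am <- arrayInd(which.max(D), dim(D))
    coord <- c(grids[[1]][am[1]], grids[[2]][am[2]], grids[[3]][am[3]])
  }
  axes <- lapply(1:3, function(a)
    list(grid = grids[[a]], density = dens[[a]] / (sum(dens[[a]]) * grid_step)))
  names(axes) <- c("x", "y", "z")
  structure(list(coord = setNames(coord, c("x", "y", "z")), axes = axes,
                 bw = bw, n_points = nrow(xyz)),
            class = "hotspot")
}

## Selected inside-STN contact coordinates + weights across a cohort, for
## one band and one state/bin power accessor. Returns n_hemi x 3 and w.
.cohort_selection <- function(cohort, band, extract) {
  xyz <- matrix(NA_real_, length(cohort), 3)
  w <- numeric(length(cohort))
  keep <- logical(length(cohort))
  for (h in seq_along(cohort)) {
    hemi <- cohort[[h]]
    if (sum(hemi$contacts$inside_stn) < 2) next   # cohort inclusion rule
    p <- extract(hemi)
    sel <- select_max_contact(p, hemi$contacts)
    xyz[h, ] <- as.numeric(hemi$contacts[sel$row, c("x", "y", "z")])
    w[h] <- max(sel$power, 0)
    keep[h] <- TRUE
  }
  list(xyz = xyz[keep, , drop = FALSE], w = w[keep], keep = keep)
}

#' Group-level hotspot time course for one band
#'
#' One hotspot per rest epoch, pre-movement epoch and 5% movement bin,
#' plus state-level hotspots (KDE over state-mean powers). Weights are
#' normalized within each state/bin across the cohort before the KDE, so
#' overall power scale does not move the hotspot.
#'
#' @param cohort a `power_cohort` (or list of per-hemisphere entries with
#'   `contacts` and `power[[band]]` = list(rest, premove, move); vector
#'   states give a single state-level hotspot, matrix states one hotspot
#'   per column).
#' @param band band name.
#' @param bw_floor,grid_step passed to [weighted_kde_hotspot()].
#' @return list with `state` (named list of `hotspot`: rest, premove,
#'   move), `move_bins` (list of per-bin hotspots), and, when epoch
#'   matrices are present, `rest_epochs` / `premove_epochs`.
#' @export
hotspot_timecourse <- function(cohort, band, bw_floor = 0.3, grid_step = 0.05) {
  getp <- function(hemi) hemi$power[[band]]
  one <- function(extract) {
    s <- .cohort_selection(cohort, band, extract)
    if (nrow(s$xyz) < 3) stopf("hotspot_timecourse: < 3 contributing hemispheres")
    weighted_kde_hotspot(s$xyz, s$w / sum(s$w), bw_floor, grid_step)
  }
  state_val <- function(v) if (is.matrix(v)) rowMeans(v) else v
  out <- list(state = list(
    rest = one(function(h) state_val(getp(h)$rest)),
    premove = one(function(h) state_val(getp(h)$premove)),
    move = one(function(h) rowMeans(getp(h)$move))
  ))
  nb <- ncol(cohort[[1]]$power[[band]]$move)
  out$move_bins <- lapply(seq_len(nb), function(b)
    one(function(h) getp(h)$move[, b]))
  for (st in c("rest", "premove")) {
    v <- cohort[[1]]$power[[band]][[st]]
    if (is.matrix(v))
      out[[paste0(st, "_epochs")]] <- lapply(seq_len(ncol(v)), function(e)
        one(function(h) getp(h)[[st]][, e]))
  }
  out
}

#' Hotspot propagation relative to a reference
#'
#' Per bin, component deltas (bin minus reference) and Euclidean
#' distance, mm.
#'
#' @param hotspots list of `hotspot` (e.g. per movement bin).
#' @param reference a `hotspot` (pre-movement or rest state).
#' @param labels optional bin labels.
#' @return data.frame of class `propagation_series`: bin, dx, dy, dz,
#'   euclid.
#' @export
propagation <- function(hotspots, reference, labels = NULL) {
  ref <- reference$coord
  out <- do.call(rbind, lapply(seq_along(hotspots), function(i) {
    d <- hotspots[[i]]$coord - ref
    data.frame(bin = if (is.null(labels)) i else labels[i],
               dx = d[1], dy = d[2], dz = d[3],
               euclid = sqrt(sum(d^2)))
  }))
  rownames(out) <- NULL
  class(out) <- c("propagation_series", "data.frame")
  out
}

#' Surrogate (random-contact) propagation test
#'
#' Builds the null by replacing each hemisphere's selected movement-state
#' contact with a uniformly random inside-STN contact (keeping the
#' observed power as weight), recomputing the cohort KDE hotspot, and
#' taking its difference from the reference hotspot. Observed propagation
#' is significant when it falls outside the two-tailed 5% band of the
#' surrogate distribution; the decision is taken via the permutation
#' p-value `p = (1 + #{null at least as extreme}) / (n + 1)` per tail
#' (the order-statistic form of the [2.5, 97.5] percentile rule, exactly
#' calibrated under exchangeability). With several bins, p-values are
#' FDR-corrected per axis across bins.
#'
#' @param cohort a `power_cohort`-style list.
#' @param band band name.
#' @param reference a `hotspot` (typically the observed pre-movement
#'   hotspot) or NULL to compute it from the cohort.
#' @param bins `"state"` for one movement-state-level test, or `"bins"`
#'   for one test per movement bin.
#' @param n number of surrogate draws (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @param axes axes tested (default x, y, z).
#' @param alpha two-tailed level (default 0.05).
#' @param bw_floor,grid_step KDE parameters.
#' @return object of class `surrogate_test`: data.frame `table` (bin,
#'   axis, observed, crit_lo, crit_hi, p, p_fdr, significant), plus
#'   `null` (draws per axis for the first bin), `n`, `reference`.
#' @export
surrogate_test <- function(cohort, band, reference = NULL,
                           bins = c("state", "bins"), n = 1000, seed = 1L,
                           axes = c("x", "y", "z"), alpha = 0.05,
                           bw_floor = 0.3, grid_step = 0.05) {
  bins <- match.arg(bins)
  if (n < 100) warnf("surrogate_test: n = %d surrogates gives unstable percentiles", n)
  getp <- function(hemi) hemi$power[[band]]
  if (is.null(reference)) {
    s <- .cohort_selection(cohort, band, function(h) {
      v <- getp(h)$premove
      if (is.matrix(v)) rowMeans(v) else v
    })
    reference <- weighted_kde_hotspot(s$xyz, s$w / sum(s$w), bw_floor, grid_step)
  }
  ## inside-contact coordinate pools per hemisphere
  pools <- lapply(cohort, function(h)
    as.matrix(h$contacts[h$contacts$inside_stn, c("x", "y", "z"), drop = FALSE]))
  extractors <- if (bins == "state")
    list(state = function(h) rowMeans(getp(h)$move))
  else {
    nbin <- ncol(cohort[[1]]$power[[band]]$move)
    setNames(lapply(seq_len(nbin), function(b) function(h) getp(h)$move[, b]),
             paste0("bin", seq_len(nbin)))
  }
  ax_i <- match(axes, c("x", "y", "z"))
  rows <- list()
  null_first <- NULL
  with_seed(seed, {
    for (bi in seq_along(extractors)) {
      s <- .cohort_selection(cohort, band, extractors[[bi]])
      obs_hot <- weighted_kde_hotspot(s$xyz, s$w / sum(s$w), bw_floor, grid_step)
      obs <- (obs_hot$coord - reference$coord)[ax_i]
      pk <- pools[s$keep]
      surr <- matrix(NA_real_, n, length(ax_i))
      for (d in seq_len(n)) {
        rx <- t(vapply(pk, function(p) p[sample.int(nrow(p), 1L), ], numeric(3)))
        sh <- weighted_kde_hotspot(rx, s$w / sum(s$w), bw_floor, grid_step)
        surr[d, ] <- (sh$coord - reference$coord)[ax_i]
      }
      if (is.null(null_first)) null_first <- surr
      for (a in seq_along(ax_i)) {
        p <- perm_p_two_tailed(obs[a], surr[, a])
        rows[[length(rows) + 1]] <- data.frame(
          bin = names(extractors)[bi], axis = axes[a], observed = obs[a],
          crit_lo = quantile(surr[, a], alpha / 2, names = FALSE),
          crit_hi = quantile(surr[, a], 1 - alpha / 2, names = FALSE),
          p = p, stringsAsFactors = FALSE)
      }
    }
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- ave(tab$p, tab$axis, FUN = fdr_adjust)
  tab$significant <- tab$p_fdr <= alpha
  structure(list(table = tab, null = null_first, n = n, reference = reference,
                 band = band, alpha = alpha),
            class = "surrogate_test")
}

#' Hotspot volatility
#'
#' Percentage of time-bin transitions at which the maximal-ERS
#' inside-STN contact changed identity; invariant under strictly
#' monotone transforms of power.
#'
#' @param power contacts x bins power matrix.
#' @param contacts contact data.frame.
#' @return volatility, % in `[0, 100]`.
#' @export
volatility <- function(power, contacts) {
  if (ncol(power) < 2) stopf("volatility: need >= 2 bins")
  sel <- vapply(seq_len(ncol(power)), function(b)
    select_max_contact(power[, b], contacts)$contact_id, numeric(1))
  100 * mean(diff(sel) != 0)
}

#' Per-hemisphere propagation between two states
#'
#' Displacement of the power-weighted centroid of inside-STN contact
#' coordinates between two states (per axis and Euclidean, mm); the
#' individual-level propagation feature used by the clinical stage.
#'
#' @param hemi one `power_cohort` entry.
#' @param band band name.
#' @param state_a,state_b state names (`"rest"`, `"premove"`, `"move"`).
#' @return named numeric: dx, dy, dz, euclid.
#' @export
per_hemisphere_propagation <- function(hemi, band, state_a = "premove",
                                       state_b = "move") {
  inside <- which(hemi$contacts$inside_stn)
  if (length(inside) < 2) stopf("per_hemisphere_propagation: < 2 inside contacts")
  pos <- as.matrix(hemi$contacts[inside, c("x", "y", "z")])
  cen <- function(state) {
    v <- hemi$power[[band]][[state]]
    if (is.matrix(v)) v <- rowMeans(v)
    w <- pmax(v[inside], 0)
    if (sum(w) <= 0) w <- rep(1, length(inside))
    colSums(pos * w) / sum(w)
  }
  d <- cen(state_b) - cen(state_a)
  c(dx = d[[1]], dy = d[[2]], dz = d[[3]], euclid = sqrt(sum(d^2)))
}

#' Magnitude-propagation ratio
#'
#' Per hemisphere and band, the ratio of normalized synchronization
#' magnitude to normalized propagation:
#' `(AUC / cohort-mean AUC) / (propagation / cohort-mean propagation)`,
#' the cohort means taken across bands and hemispheres. The per-band
#' signed-rank test compares the ratio against 1 (FDR-corrected).
#'
#' @param magnitude data.frame hemisphere_id, band, auc.
#' @param prop data.frame hemisphere_id, band, propagation (mm).
#' @return list with `table` (per hemisphere x band ratios) and `tests`
#'   (per band: median ratio, p, p_fdr).
#' @export
magnitude_propagation_ratio <- function(magnitude, prop) {
  m <- merge(magnitude, prop, by = c("hemisphere_id", "band"))
  mean_auc <- mean(m$auc)
  mean_prop <- mean(m$propagation)
  if (mean_auc == 0 || mean_prop == 0)
    stopf("magnitude_propagation_ratio: degenerate cohort means")
  ok <- m$propagation > 0
  excl <- m[!ok, , drop = FALSE]
  m <- m[ok, , drop = FALSE]
  m$ratio <- (m$auc / mean_auc) / (m$propagation / mean_prop)
  tests <- do.call(rbind, lapply(split(m, m$band), function(d) {
    wt <- suppressWarnings(wilcox.test(d$ratio - 1))
    data.frame(band = d$band[1], median_ratio = median(d$ratio),
               mean_ratio = mean(d$ratio), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  tests$p_fdr <- fdr_adjust(tests$p)
  rownames(tests) <- NULL
  list(table = m, tests = tests, excluded = excl)
}

#' Null calibration of the surrogate propagation test
#'
#' Repeatedly generates null cohorts (spatially exchangeable contacts,
#' band sources static between pre-movement and movement), runs the
#' random-contact surrogate propagation test on one axis per cohort, and
#' returns the empirical two-tailed rejection rate at the 5% critical
#' values -- which should sit at its nominal level.
#'
#' @param n_replicates null cohorts (default 400).
#' @param n_hemispheres hemispheres per cohort (default 30).
#' @param n_surrogates surrogate draws per test (default 200).
#' @param seed master seed.
#' @param band band tested (default "HG").
#' @param axis axis tested (default "z").
#' @param alpha two-tailed level.
#' @return list: `rejection_rate` (%), `n_replicates`, `p_values`.
#' @export
calibrate_surrogate_null <- function(n_replicates = 400, n_hemispheres = 30,
                                     n_surrogates = 200, seed = 1L,
                                     band = "HG", axis = "z", alpha = 0.05) {
  ps <- vapply(seq_len(n_replicates), function(r) {
    pc <- simulate_power_cohort(n_hemispheres, seed = derive_seed(seed, 3L * r),
                                spatial_null = TRUE)
    st <- surrogate_test(pc, band, reference = NULL, bins = "state",
                         n = n_surrogates, seed = derive_seed(seed, 3L * r + 1L),
                         axes = axis)
    st$table$p[1]
  }, numeric(1))
  list(rejection_rate = 100 * mean(ps <= alpha), n_replicates = n_replicates,
       p_values = ps)
}

#' Convert per-hemisphere ERS tensors to the band-power cohort form
#'
#' Weights for the spatial stage are the nonnegative part of the
#' state-resolved band z values (synchronization magnitude in baseline
#' SDs), with a small floor so that a fully idle state still yields a
#' defined (uniform) selection.
#'
#' @param ers_list list of `ers_tensor`.
#' @return a `power_cohort`-style list.
#' @export
ers_to_power_cohort <- function(ers_list) {
  out <- lapply(ers_list, function(e) {
    bands <- e$bands$band
    pw <- lapply(seq_along(bands), function(b) list(
      rest = pmax(e$rest_epochs[, b, , drop = TRUE], 0) + 1e-9,
      premove = pmax(e$premove_epochs[, b, , drop = TRUE], 0) + 1e-9,
      move = pmax(matrix(e$move[, b, ], nrow = 8), 0) + 1e-9))
    names(pw) <- bands
    list(hemisphere_id = e$hemisphere_id, contacts = e$contacts, power = pw)
  })
  names(out) <- vapply(ers_list, `[[`, "", "hemisphere_id")
  class(out) <- "power_cohort"
  out
}
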