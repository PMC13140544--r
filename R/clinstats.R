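TRANSITIONS <- c(r2p = "rest>premove", r2m = "rest>move", p2m = "premove>move")

#' Assemble the hemisphere-level clinical feature matrix
#'
#' 24 features per hemisphere: 4 high-frequency bands x 2 feature types
#' x 3 motor-state transitions (rest->premove, rest->move,
#' premove->move). The power feature is the difference of inside-contact
#' state-mean band power across the transition; the propagation feature
#' is the per-hemisphere weighted-centroid displacement (Euclidean, mm)
#' across the transition. Targets (`updrs3_off`, `pct_improvement`) are
#' joined from the clinical records on hemisphere_id.
#'
#' @param cohort a `power_cohort`-style list.
#' @param clinical `clinical_records` data.frame.
#' @param bands band names (default the four high-frequency bands).
#' @return object of class `feature_matrix`: `X` (n x 24 data.frame),
#'   `updrs3_off`, `pct_improvement`, `hemisphere_id`.
#' @export
build_feature_matrix <- function(cohort, clinical,
                                 bands = stn_bands("high")$band) {
  ids <- vapply(cohort, function(h) h$hemisphere_id, "")
  miss <- setdiff(ids, clinical$hemisphere_id)
  if (length(miss))
    stopf("build_feature_matrix: unmatched hemisphere(s): %s",
          paste(miss, collapse = ", "))
  states <- list(r2p = c("rest", "premove"), r2m = c("rest", "move"),
                 p2m = c("premove", "move"))
  rows <- lapply(cohort, function(h) {
    inside <- h$contacts$inside_stn
    smean <- function(band, state) {
      v <- h$power[[band]][[state]]
      if (is.matrix(v)) v <- rowMeans(v)
      mean(v[inside])
    }
    vals <- c()
    for (b in bands) for (tn in names(states)) {
      st <- states[[tn]]
      vals[paste(b, "power", tn, sep = "_")] <- smean(b, st[2]) - smean(b, st[1])
      vals[paste(b, "prop", tn, sep = "_")] <-
        per_hemisphere_propagation(h, b, st[1], st[2])[["euclid"]]
    }
    vals
  })
  X <- as.data.frame(do.call(rbind, rows))
  rownames(X) <- NULL
  cl <- clinical[match(ids, clinical$hemisphere_id), ]
  if (any(is.na(cl$updrs3_off)) || any(is.na(cl$pct_improvement)))
    stopf("build_feature_matrix: missing clinical targets")
  structure(list(X = X, updrs3_off = cl$updrs3_off,
                 pct_improvement = cl$pct_improvement, hemisphere_id = ids),
            class = "feature_matrix")
}

#' Spearman correlation with percentile-bootstrap CI
#'
#' Rank correlation with an asymptotic two-sided p-value and a 95%
#' percentile confidence interval over paired bootstrap resamples
#' (default 5000). FDR across a grid of correlations is the caller's
#' responsibility.
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @param cfg a `stats_config` (`n_bootstrap`, `ci_level`).
#' @param seed RNG seed.
#' @return list: `rho`, `p`, `ci` (length 2), `n`.
#' @export
spearman_bootstrap <- function(x, y, cfg = stats_config(), seed = 1L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stopf("spearman_bootstrap: need n >= 5")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("spearman_bootstrap: ties-only input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  boot <- with_seed(seed, {
    vapply(seq_len(cfg$n_bootstrap), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(rank(x[idx]), rank(y[idx])))
    }, numeric(1))
  })
  a <- (1 - cfg$ci_level) / 2
  list(rho = unname(ct$estimate), p = ct$p.value,
       ci = quantile(boot, c(a, 1 - a), names = FALSE, na.rm = TRUE), n = n)
}

#' Correlate features with clinical targets (FDR-corrected grid)
#'
#' Runs [spearman_bootstrap()] for every feature column against each
#' clinical target and FDR-corrects p-values within each target.
#'
#' @param fm a `feature_matrix`.
#' @param cfg a `stats_config`.
#' @param seed RNG seed.
#' @return data.frame: target, feature, rho, p, p_fdr, ci_lo, ci_hi,
#'   significant.
#' @export
clinical_correlations <- function(fm, cfg = stats_config(), seed = 1L) {
  targets <- list(updrs3_off = fm$updrs3_off, pct_improvement = fm$pct_improvement)
  out <- list()
  k <- 0L
  for (tg in names(targets)) {
    for (f in colnames(fm$X)) {
      k <- k + 1L
      sb <- spearman_bootstrap(fm$X[[f]], targets[[tg]], cfg,
                               seed = derive_seed(seed, k))
      out[[k]] <- data.frame(target = tg, feature = f, rho = sb$rho, p = sb$p,
                             ci_lo = sb$ci[1], ci_hi = sb$ci[2],
                             stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$p_fdr <- ave(tab$p, tab$target, FUN = fdr_adjust)
  tab$significant <- tab$p_fdr <= cfg$alpha
  tab
}

#' Comparison-test battery on ERS summaries
#'
#' Repeated-measures ANOVA across bands on AUC (within-subject band
#' factor with hemisphere blocking) followed by Tukey's post hoc on the
#' band effect; paired Wilcoxon signed-rank tests of the timing deltas
#' (ERS peak vs EMG peak, ERS peak vs beta-ERD trough) per band. All
#' p-values FDR-corrected within their family; effect directions
#' reported.
#'
#' @param summaries stacked `ers_summary` rows (>= 3 hemispheres).
#' @return list: `anova` (band F-test), `tukey` (pairwise band
#'   contrasts), `signed_rank` (per band x delta).
#' @export
comparison_battery <- function(summaries) {
  if (length(unique(summaries$hemisphere_id)) < 3)
    stopf("comparison_battery: need >= 3 hemispheres")
  d <- summaries
  d$band <- factor(d$band)
  d$hemi <- factor(d$hemisphere_id)
  fit <- aov(auc_total ~ band + hemi, data = d)
  an <- summary(fit)[[1]]
  anova_row <- data.frame(effect = "band", df = an["band", "Df"],
                          F = an["band", "F value"], p = an["band", "Pr(>F)"])
  tk <- TukeyHSD(fit, which = "band")$band
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      p = tk[, "p adj"], stringsAsFactors = FALSE)
  tukey$direction <- ifelse(tukey$diff > 0, "first_greater", "second_greater")
  rownames(tukey) <- NULL
  sr <- list()
  for (col in c("delta_ers_emg", "delta_ers_erd")) {
    for (b in levels(d$band)) {
      v <- d[[col]][d$band == b]
      if (all(!is.finite(v))) next
      wt <- suppressWarnings(wilcox.test(v[is.finite(v)]))
      sr[[length(sr) + 1]] <- data.frame(
        delta = col, band = b, median = median(v, na.rm = TRUE),
        p = wt$p.value, direction = ifelse(median(v, na.rm = TRUE) > 0,
                                           "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  signed_rank <- do.call(rbind, sr)
  signed_rank$p_fdr <- fdr_adjust(signed_rank$p)
  list(anova = anova_row, tukey = tukey, signed_rank = signed_rank)
}
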