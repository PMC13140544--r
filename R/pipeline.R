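#' Pipeline run configuration
#'
#' A plain list of stage configurations plus paths and the master seed;
#' per-stage seeds are derived from the master seed with a counter
#' scheme so stages can be re-run independently and reproducibly.
#'
#' @param cohort_dir cohort bundle directory.
#' @param out_dir results directory.
#' @param seed master seed.
#' @param n_hemispheres,n_trials,fs_raw synthetic-cohort size (simulate
#'   stage only).
#' @param use_true_events use generator event truth instead of EMG burst
#'   detection.
#' @param preproc,spectral,stats,boost stage configuration objects.
#' @param n_surrogates surrogate draws for the propagation test.
#' @param run_boost run the LOOCV boosting stage (slowest stage).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_dir = "cohort", out_dir = "results", seed = 1L,
                       n_hemispheres = 63, n_trials = 18, fs_raw = 2048,
                       use_true_events = FALSE,
                       preproc = preproc_config(), spectral = spectral_config(),
                       stats = stats_config(), boost = boost_config(),
                       n_surrogates = 1000, run_boost = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Recognized top-level keys: `cohort_dir`, `out_dir`, `seed`,
#' `n_hemispheres`, `n_trials`, `fs_raw`, `use_true_events`,
#' `n_surrogates`, `n_bootstrap`, `n_permutations`, `run_boost`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in c("cohort_dir", "out_dir", "seed", "n_hemispheres", "n_trials",
              "fs_raw", "use_true_events", "n_surrogates", "run_boost"))
    if (!is.null(y[[k]])) cfg[[k]] <- y[[k]]
  if (!is.null(y$n_bootstrap)) cfg$stats$n_bootstrap <- y$n_bootstrap
  if (!is.null(y$n_permutations)) cfg$boost$n_permutations <- y$n_permutations
  cfg
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

## Shared per-hemisphere analysis: preprocess + ERS tensors.
.analyze_hemispheres <- function(bundle, cfg) {
  ers_list <- list()
  rejections <- list()
  for (id in names(bundle$recordings)) {
    pre <- preprocess_recording(bundle$recordings[[id]], cfg$preproc,
                                use_true_events = cfg$use_true_events)
    .log_stage("preprocess", "%s: %d kept / %d dropped / %d rejected trials",
               id, length(pre$epochs), nrow(pre$dropped), nrow(pre$rejection_log))
    ers_list[[id]] <- compute_hemisphere_ers(pre, cfg$spectral)
    if (nrow(pre$rejection_log))
      rejections[[id]] <- cbind(hemisphere_id = id, pre$rejection_log)
  }
  list(ers = ers_list,
       rejections = if (length(rejections)) do.call(rbind, rejections)
       else data.frame(hemisphere_id = character(0)))
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (generate + write a synthetic cohort bundle),
#' `preprocess`, `ers`, `hotspots`, `propagation`, `clinical` (each
#' runs the pipeline up to that stage and writes the corresponding
#' result tables), `report`/`all` (everything). Every stage is
#' deterministic given the master seed.
#'
#' @param command subcommand string.
#' @param config a `run_config`, or path to a YAML file.
#' @param seed optional master-seed override.
#' @return invisibly, the list of result tables written (if any).
#' @export
run_pipeline <- function(command = "all", config = run_config(), seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  cmd <- match.arg(command, c("simulate", "preprocess", "ers", "hotspots",
                              "propagation", "clinical", "report", "all"))
  if (cmd == "simulate") {
    sc <- synth_config(n_hemispheres = config$n_hemispheres,
                       n_trials = config$n_trials, fs_raw = config$fs_raw,
                       rng_seed = config$seed)
    .log_stage("simulate", "generating %d hemispheres at %g Hz",
               sc$n_hemispheres, sc$fs_raw)
    cohort <- simulate_cohort(sc)
    write_cohort_bundle(cohort, config$cohort_dir)
    .log_stage("simulate", "bundle written to %s", config$cohort_dir)
    return(invisible(NULL))
  }
  if (!dir.exists(config$cohort_dir))
    stopf("run_pipeline: cohort directory %s not found (run `simulate` first)",
          config$cohort_dir)
  bundle <- read_cohort_bundle(config$cohort_dir)
  hemis <- .analyze_hemispheres(bundle, config)
  tables <- list(rejection_log = hemis$rejections)
  if (cmd == "preprocess") {
    write_results(tables, config$out_dir, config, config$seed)
    return(invisible(tables))
  }
  summaries <- do.call(rbind, lapply(hemis$ers, summarize_ers))
  rownames(summaries) <- NULL
  tables$ers_summary <- summaries
  battery <- comparison_battery(summaries)
  tables$battery_anova <- battery$anova
  tables$battery_tukey <- battery$tukey
  tables$battery_signed_rank <- battery$signed_rank
  if (cmd == "ers") {
    write_results(tables, config$out_dir, config, config$seed)
    return(invisible(tables))
  }
  pw <- ers_to_power_cohort(hemis$ers)
  bands_hi <- stn_bands("high")$band
  hs_rows <- list(); prop_rows <- list(); surr_rows <- list(); vol_rows <- list()
  for (b in bands_hi) {
    tc <- hotspot_timecourse(pw, b)
    for (st in names(tc$state))
      hs_rows[[paste(b, st)]] <- data.frame(
        band = b, state = st, x = tc$state[[st]]$coord[1],
        y = tc$state[[st]]$coord[2], z = tc$state[[st]]$coord[3])
    pr <- propagation(tc$move_bins, tc$state$premove,
                      labels = seq(0, 100, length.out = length(tc$move_bins)))
    prop_rows[[b]] <- cbind(band = b, pr)
    if (cmd %in% c("propagation", "clinical", "report", "all")) {
      st_test <- surrogate_test(pw, b, reference = tc$state$premove,
                                bins = "state", n = config$n_surrogates,
                                seed = derive_seed(config$seed, match(b, bands_hi)))
      surr_rows[[b]] <- cbind(band = b, st_test$table)
    }
    for (id in names(pw)) {
      h <- pw[[id]]
      vol_rows[[paste(b, id)]] <- data.frame(
        hemisphere_id = id, band = b,
        rest = volatility(h$power[[b]]$rest, h$contacts),
        premove = volatility(h$power[[b]]$premove, h$contacts),
        move = volatility(h$power[[b]]$move, h$contacts))
    }
  }
  tables$hotspots <- do.call(rbind, hs_rows)
  tables$volatility <- do.call(rbind, vol_rows)
  rownames(tables$hotspots) <- rownames(tables$volatility) <- NULL
  if (cmd == "hotspots") {
    write_results(tables, config$out_dir, config, config$seed)
    return(invisible(tables))
  }
  tables$propagation <- do.call(rbind, prop_rows)
  tables$surrogate_tests <- do.call(rbind, surr_rows)
  rownames(tables$propagation) <- rownames(tables$surrogate_tests) <- NULL
  prop_hemi <- do.call(rbind, lapply(names(pw), function(id) {
    do.call(rbind, lapply(bands_hi, function(b) {
      d <- per_hemisphere_propagation(pw[[id]], b)
      data.frame(hemisphere_id = id, band = b, propagation = d[["euclid"]])
    }))
  }))
  ratio <- magnitude_propagation_ratio(
    data.frame(hemisphere_id = summaries$hemisphere_id, band = summaries$band,
               auc = summaries$auc_total), prop_hemi)
  tables$ratio <- ratio$table
  tables$ratio_tests <- ratio$tests
  if (cmd == "propagation") {
    write_results(tables, config$out_dir, config, config$seed)
    return(invisible(tables))
  }
  if (is.null(bundle$clinical))
    stopf("run_pipeline: clinical.tsv missing from %s", config$cohort_dir)
  fm <- build_feature_matrix(pw, bundle$clinical)
  tables$features <- cbind(hemisphere_id = fm$hemisphere_id, fm$X,
                           updrs3_off = fm$updrs3_off,
                           pct_improvement = fm$pct_improvement)
  tables$correlations <- clinical_correlations(fm, config$stats,
                                               seed = derive_seed(config$seed, 101L))
  if (isTRUE(config$run_boost) && nrow(fm$X) >= 10) {
    boosts <- lapply(list(updrs3_off = fm$updrs3_off,
                          pct_improvement = fm$pct_improvement), function(yy) {
      loocv_evaluate(fm$X, yy, config$boost, seed = derive_seed(config$seed, 202L))
    })
    tables$boost_summary <- do.call(rbind, lapply(names(boosts), function(tg)
      data.frame(target = tg, pearson_r = boosts[[tg]]$pearson_r,
                 rmse = boosts[[tg]]$rmse)))
    tables$boost_importance <- do.call(rbind, lapply(names(boosts), function(tg)
      data.frame(target = tg, feature = names(boosts[[tg]]$importance),
                 importance = unname(boosts[[tg]]$importance))))
  }
  write_results(tables, config$out_dir, config, config$seed)
  .log_stage(cmd, "results written to %s", config$out_dir)
  invisible(tables)
}
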