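#' Stagewise least-squares gradient boosting (LSBoost)
#'
#' F0 is the training mean; each cycle fits a depth-limited regression
#' tree (rpart, anova) to the current residuals and adds its shrunken
#' prediction. Training MSE is non-increasing in the number of cycles
#' for any learning rate in (0, 2).
#'
#' @param X predictor data.frame or matrix (no missing values).
#' @param y numeric response.
#' @param learn_rate shrinkage in (0.3, 0.6) per the search range (other
#'   values allowed programmatically).
#' @param n_cycles boosting cycles.
#' @param depth base-tree maximum depth (default 2).
#' @param min_split rpart minsplit (default 5).
#' @return object of class `lsboost`: `f0`, `trees`, `learn_rate`,
#'   `train_mse` (per cycle), `feature_names`.
#' @export
lsboost_fit <- function(X, y, learn_rate = 0.45, n_cycles = 100, depth = 2,
                        min_split = 5) {
  X <- as.data.frame(X)
  if (any(!is.finite(as.matrix(X))) || any(!is.finite(y)))
    stopf("lsboost_fit: non-finite inputs")
  stopifnot(nrow(X) == length(y), n_cycles >= 1)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = min_split,
                               minbucket = 2, xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  f0 <- mean(y)
  fhat <- rep(f0, length(y))
  trees <- vector("list", n_cycles)
  mse <- numeric(n_cycles)
  d <- X
  for (m in seq_len(n_cycles)) {
    d$.r <- y - fhat
    tr <- rpart::rpart(.r ~ ., data = d, method = "anova", control = ctrl)
    fhat <- fhat + learn_rate * predict(tr, d)
    trees[[m]] <- tr
    mse[m] <- mean((y - fhat)^2)
  }
  structure(list(f0 = f0, trees = trees, learn_rate = learn_rate,
                 train_mse = mse, feature_names = colnames(X)),
            class = "lsboost")
}

#' Predict from an LSBoost model
#'
#' @param object an `lsboost` model.
#' @param newdata predictor data.frame/matrix.
#' @param n_cycles use only the first `n_cycles` trees (staged
#'   prediction; default all).
#' @param all_stages if TRUE return an n x n_cycles matrix of staged
#'   predictions.
#' @param ... unused.
#' @return numeric predictions (or staged matrix).
#' @export
predict.lsboost <- function(object, newdata, n_cycles = length(object$trees),
                            all_stages = FALSE, ...) {
  newdata <- as.data.frame(newdata)
  pred <- rep(object$f0, nrow(newdata))
  if (all_stages) {
    out <- matrix(NA_real_, nrow(newdata), length(object$trees))
    for (m in seq_along(object$trees)) {
      pred <- pred + object$learn_rate * predict(object$trees[[m]], newdata)
      out[, m] <- pred
    }
    return(out)
  }
  for (m in seq_len(n_cycles))
    pred <- pred + object$learn_rate * predict(object$trees[[m]], newdata)
  unname(pred)
}

## Split-gain importance of one rpart tree: for every internal node,
## the deviance (SS) reduction dev(node) - dev(left) - dev(right),
## attributed to the primary split variable.
.tree_importance <- function(tree, feature_names) {
  imp <- setNames(numeric(length(feature_names)), feature_names)
  fr <- tree$frame
  if (nrow(fr) <= 1) return(imp)
  ids <- as.integer(rownames(fr))
  for (i in which(fr$var != "<leaf>")) {
    node <- ids[i]
    li <- match(2L * node, ids); ri <- match(2L * node + 1L, ids)
    if (is.na(li) || is.na(ri)) next
    gain <- fr$dev[i] - fr$dev[li] - fr$dev[ri]
    v <- as.character(fr$var[i])
    imp[v] <- imp[v] + max(gain, 0)
  }
  imp
}

#' Feature importance of an LSBoost model
#'
#' Total squared-error reduction attributed to splits on each feature,
#' summed over all trees (the contribution of each feature to reducing
#' prediction error across boosting iterations). Nonnegative; zero for
#' unused features.
#'
#' @param model an `lsboost` model.
#' @param normalize scale to sum 1 when positive (default FALSE).
#' @return named numeric vector.
#' @export
lsboost_importance <- function(model, normalize = FALSE) {
  imp <- Reduce(`+`, lapply(model$trees, .tree_importance,
                            feature_names = model$feature_names))
  if (normalize && sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

## Inner hyperparameter selection on rows `rows`: k-fold CV over
## learn_rates, evaluating every n_cycles candidate from one staged fit
## per learning rate. Returns list(learn_rate, n_cycles).
.select_hyper <- function(X, y, rows, cfg, seed) {
  folds <- with_seed(seed, sample(rep_len(seq_len(cfg$inner_folds), length(rows))))
  err <- array(0, c(length(cfg$learn_rates), length(cfg$n_cycles_grid)))
  for (k in seq_len(cfg$inner_folds)) {
    tr <- rows[folds != k]; va <- rows[folds == k]
    if (length(va) == 0 || length(tr) < 5) next
    for (li in seq_along(cfg$learn_rates)) {
      m <- lsboost_fit(X[tr, , drop = FALSE], y[tr], cfg$learn_rates[li],
                       n_cycles = max(cfg$n_cycles_grid), depth = cfg$max_depth)
      staged <- predict(m, X[va, , drop = FALSE], all_stages = TRUE)
      for (ci in seq_along(cfg$n_cycles_grid))
        err[li, ci] <- err[li, ci] +
          mean((y[va] - staged[, cfg$n_cycles_grid[ci]])^2) / cfg$inner_folds
    }
  }
  best <- arrayInd(which.min(err), dim(err))
  list(learn_rate = cfg$learn_rates[best[1]], n_cycles = cfg$n_cycles_grid[best[2]])
}

#' Leave-one-out cross-validated LSBoost evaluation
#'
#' For each left-out row, hyperparameters (learning rate, cycles) are
#' selected by inner cross-validation on the training fold only (no
#' leakage), the model is refit on the training fold and the held-out
#' prediction recorded. Reports Pearson r and RMSE between actual and
#' predicted, per-fold hyperparameters, and the fold-mean feature
#' importance.
#'
#' @param X predictors (n x p), no missing values.
#' @param y numeric response, length n >= 10.
#' @param cfg a `boost_config`.
#' @param seed master seed (fold-level seeds derived).
#' @return object of class `boost_report`: `predictions`, `actual`,
#'   `pearson_r`, `rmse`, `importance`, `per_fold` data.frame.
#' @export
loocv_evaluate <- function(X, y, cfg = boost_config(), seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 10) stopf("loocv_evaluate: need n >= 10")
  preds <- numeric(n)
  imps <- matrix(0, n, ncol(X), dimnames = list(NULL, colnames(X)))
  hp <- data.frame(fold = seq_len(n), learn_rate = NA_real_, n_cycles = NA_integer_)
  for (i in seq_len(n)) {
    rows <- setdiff(seq_len(n), i)
    sel <- .select_hyper(X, y, rows, cfg, derive_seed(seed, i))
    m <- lsboost_fit(X[rows, , drop = FALSE], y[rows], sel$learn_rate,
                     sel$n_cycles, depth = cfg$max_depth)
    preds[i] <- predict(m, X[i, , drop = FALSE])
    imps[i, ] <- lsboost_importance(m)
    hp$learn_rate[i] <- sel$learn_rate
    hp$n_cycles[i] <- sel$n_cycles
  }
  structure(list(predictions = preds, actual = y,
                 pearson_r = suppressWarnings(cor(preds, y)),
                 rmse = sqrt(mean((preds - y)^2)),
                 importance = colMeans(imps), per_fold = hp),
            class = "boost_report")
}

#' @export
print.boost_report <- function(x, ...) {
  cat("LOOCV boosting report: n =", length(x$actual),
      sprintf("| Pearson r = %.3f | RMSE = %.2f\n", x$pearson_r, x$rmse))
  top <- sort(x$importance, decreasing = TRUE)
  cat("top features:", paste(names(head(top, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test of feature importance + top-rank probabilities
#'
#' The observed model (hyperparameters selected once by inner CV on the
#' full data) is compared against a null distribution of importances
#' obtained by refitting on label-shuffled data; per-feature
#' p = fraction of null importances >= observed, FDR-corrected across
#' features. Top-rank probabilities are estimated over bootstrap seed
#' replicates: the fraction of replicates in which each feature -- and
#' each group under the band / feature-type / transition partitions of
#' feature names of the form `<band>_<type>_<transition>` -- attains the
#' maximal importance.
#'
#' @param X predictors.
#' @param y response.
#' @param cfg a `boost_config` (`n_permutations` label shuffles,
#'   `n_rank_replicates` bootstrap replicates).
#' @param seed RNG seed.
#' @return list: `observed` importance, `p`, `p_fdr`, `top_rank`
#'   (per feature), `group_top_rank` (list of per-partition probability
#'   tables, each summing to 1), `hyper`.
#' @export
importance_permutation_test <- function(X, y, cfg = boost_config(), seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  sel <- .select_hyper(X, y, seq_len(n), cfg, derive_seed(seed, 0L))
  fit1 <- function(yy, rows = seq_len(n))
    lsboost_importance(lsboost_fit(X[rows, , drop = FALSE], yy[rows],
                                   sel$learn_rate, sel$n_cycles,
                                   depth = cfg$max_depth))
  obs <- fit1(y)
  null <- with_seed(derive_seed(seed, 1L), {
    t(vapply(seq_len(cfg$n_permutations), function(i) fit1(sample(y)),
             numeric(ncol(X))))
  })
  p <- vapply(seq_len(ncol(X)), function(j)
    (1 + sum(null[, j] >= obs[j])) / (cfg$n_permutations + 1), numeric(1))
  names(p) <- colnames(X)
  ## top-rank probabilities over bootstrap replicates
  top <- with_seed(derive_seed(seed, 2L), {
    vapply(seq_len(cfg$n_rank_replicates), function(r) {
      rows <- sample.int(n, n, replace = TRUE)
      which.max(fit1(y, rows))
    }, integer(1))
  })
  top_rank <- tabulate(top, ncol(X)) / cfg$n_rank_replicates
  names(top_rank) <- colnames(X)
  parts <- strsplit(colnames(X), "_", fixed = TRUE)
  group_top <- NULL
  if (all(lengths(parts) == 3)) {
    lab <- function(k) vapply(parts, `[[`, "", k)
    group_top <- lapply(setNames(1:3, c("band", "feature_type", "transition")),
                        function(k) {
                          g <- lab(k)
                          tapply(top_rank, g, sum)
                        })
  }
  list(observed = obs, p = p, p_fdr = fdr_adjust(p), top_rank = top_rank,
       group_top_rank = group_top, hyper = sel, null_importance = null)
}
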