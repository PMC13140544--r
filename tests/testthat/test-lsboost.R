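test_that("boosting training loss is monotone non-increasing", {
  set.seed(1)
  X <- as.data.frame(matrix(rnorm(60 * 6), 60))
  y <- X[[1]] * 2 + rnorm(60, 0, 0.5)
  m <- lsboost_fit(X, y, learn_rate = 0.45, n_cycles = 120)
  expect_true(all(diff(m$train_mse) <= 1e-10))
  expect_lte(m$train_mse[120], m$train_mse[30])
})

test_that("constant targets give constant predictions and zero importances", {
  X <- as.data.frame(matrix(rnorm(40 * 4), 40))
  m <- lsboost_fit(X, rep(3.5, 40), n_cycles = 30)
  expect_equal(unname(predict(m, X)), rep(3.5, 40))
  expect_true(all(lsboost_importance(m) == 0))
})

test_that("a dominant linear feature wins the importance ranking across seeds", {
  wins <- vapply(1:15, function(s) {
    set.seed(s)
    X <- as.data.frame(matrix(rnorm(60 * 12), 60))
    y <- 3 * X[[1]] + rnorm(60, 0, 0.7)
    names(which.max(lsboost_importance(lsboost_fit(X, y, n_cycles = 60))))
  }, "")
  expect_gt(mean(wins == "V1"), 0.8)
})

test_that("importances are nonnegative and zero for unused features", {
  set.seed(2)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(0, 50))
  y <- X$a + rnorm(50, 0, 0.3)
  imp <- lsboost_importance(lsboost_fit(X, y, n_cycles = 40))
  expect_true(all(imp >= 0))
  expect_equal(unname(imp["c"]), 0)   # constant column can never split
})

test_that("non-finite inputs are rejected", {
  X <- data.frame(a = c(1, NA, 3))
  expect_error(lsboost_fit(X, c(1, 2, 3)), "non-finite")
  expect_error(lsboost_fit(data.frame(a = 1:3), c(1, Inf, 3)), "non-finite")
})

test_that("staged predictions equal truncated-model predictions", {
  set.seed(3)
  X <- as.data.frame(matrix(rnorm(40 * 3), 40))
  y <- X[[2]] + rnorm(40, 0, 0.4)
  m <- lsboost_fit(X, y, n_cycles = 50)
  staged <- predict(m, X, all_stages = TRUE)
  expect_equal(staged[, 20], predict(m, X, n_cycles = 20))
  expect_equal(staged[, 50], predict(m, X))
})

test_that("LOOCV is deterministic and honest under a poisoning test", {
  set.seed(4)
  n <- 16
  X <- as.data.frame(matrix(rnorm(n * 4), n))
  y <- X[[1]] + rnorm(n, 0, 0.4)
  cfg <- boost_config(learn_rates = c(0.45), n_cycles_grid = c(30, 60),
                      inner_folds = 3)
  r1 <- loocv_evaluate(X, y, cfg, seed = 9)
  r2 <- loocv_evaluate(X, y, cfg, seed = 9)
  expect_identical(r1$predictions, r2$predictions)
  expect_length(r1$predictions, n)
  ## poisoning: altering y_i must not change the held-out prediction for i
  i <- 5
  y2 <- y; y2[i] <- y2[i] + 50
  r3 <- loocv_evaluate(X, y2, cfg, seed = 9)
  expect_equal(r3$predictions[i], r1$predictions[i], tolerance = 1e-12)
  ## but other folds see the poisoned row in training, so they may move
  expect_false(isTRUE(all.equal(r3$predictions[-i], r1$predictions[-i])))
})

test_that("LOOCV recovers a strong planted linear signal", {
  set.seed(6)
  n <- 40
  X <- as.data.frame(matrix(rnorm(n * 8), n))
  y <- X[[1]] + X[[2]] + rnorm(n, 0, 1)   # R^2 ~ 2/3
  cfg <- boost_config(learn_rates = c(0.3, 0.6), n_cycles_grid = c(30, 75),
                      inner_folds = 3)
  r <- loocv_evaluate(X, y, cfg, seed = 2)
  expect_gt(r$pearson_r, 0.4)
})

test_that("permutation importance p-values are calibrated-ish under the null and expose planted structure", {
  set.seed(7)
  n <- 36
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  colnames(X) <- paste(rep(c("HG", "FG"), each = 3), "prop",
                       c("r2p", "r2m", "p2m"), sep = "_")
  y_sig <- 2.5 * X[["FG_prop_p2m"]] + rnorm(n, 0, 0.6)
  cfg <- boost_config(learn_rates = 0.45, n_cycles_grid = c(30, 60),
                      n_permutations = 60, n_rank_replicates = 25)
  r <- importance_permutation_test(X, y_sig, cfg, seed = 3)
  expect_equal(names(which.min(r$p)), "FG_prop_p2m")
  expect_equal(names(which.max(r$top_rank)), "FG_prop_p2m")
  ## group partitions are probability distributions
  for (g in r$group_top_rank) expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(names(which.max(r$group_top_rank$transition)), "p2m")
})
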