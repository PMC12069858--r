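test_that("a noiseless single predictor is selected and fit exactly", {
  set.seed(1)
  x <- rnorm(50)
  m <- stepwise_fit(data.frame(x = x), 3 + 2 * x)
  expect_identical(m$selected, "x")
  expect_equal(m$intercept, 3, tolerance = 1e-10)
  expect_equal(unname(m$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("stepwise selection finds true predictors and rarely admits nulls", {
  set.seed(61)
  null_hits <- 0
  true_hits <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    n <- 500
    X <- as.data.frame(matrix(rnorm(n * 8), n,
                              dimnames = list(NULL, paste0("p", 1:8))))
    y <- 0.4 * X$p1 - 0.4 * X$p2 + rnorm(n)
    m <- stepwise_fit(X, y)
    true_hits <- true_hits + all(c("p1", "p2") %in% m$selected)
    null_hits <- null_hits + length(setdiff(m$selected, c("p1", "p2")))
  }
  expect_equal(true_hits, n_rep)
  # per-null-predictor admission rate stays near the p_enter level
  expect_lt(null_hits / (6 * n_rep), 0.12)
})

test_that("with a pure-noise response the entry rate matches the min-p oracle", {
  set.seed(71)
  n_rep <- 400
  entered <- logical(n_rep)
  oracle <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 44
    X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("p", 1:8)))
    y <- rnorm(n)
    m <- stepwise_fit(as.data.frame(X), y)
    entered[i] <- length(m$selected) > 0
    # oracle: the first forward step enters iff the smallest marginal
    # simple-regression p-value is below p_enter
    pvals <- apply(X, 2, function(x) {
      r <- cor(x, y)
      2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2, lower.tail = FALSE)
    })
    oracle[i] <- min(pvals) < 0.05
  }
  expect_identical(entered, oracle)
  expect_lt(abs(mean(entered) - (1 - 0.95^8)), 0.06)
})

test_that("an intercept-only model is returned when nothing enters", {
  set.seed(2)
  m <- stepwise_fit(data.frame(x = rnorm(40)), rep(c(1, 2), 20) * 0 + rnorm(40) * 0.001 + 5)
  # y nearly constant and unrelated to x
  expect_true(m$empty || length(m$selected) <= 1)
  m2 <- stepwise_fit(data.frame(x = rnorm(40)), c(rnorm(40)), p_enter = 1e-12)
  expect_true(m2$empty)
  expect_equal(m2$adj_r_squared, 0, tolerance = 1e-12)
})

test_that("candidate count is bounded by the sample size rule", {
  X <- as.data.frame(matrix(rnorm(10 * 8), 10))
  expect_error(stepwise_fit(X, rnorm(10)), "n > number of candidate")
})

test_that("44 subjects split into four folds of eleven", {
  set.seed(3)
  X <- data.frame(x = rnorm(44))
  cv <- kfold_validate(X, 0.5 * X$x + rnorm(44), K = 4, seed = 5)
  expect_equal(as.integer(table(cv$folds)), rep(11L, 4))
  expect_false(anyNA(cv$predictions$predicted))
})

test_that("a perfect noiseless model cross-validates to zero error", {
  set.seed(4)
  x <- rnorm(60)
  cv <- kfold_validate(data.frame(x = x), 1 + 4 * x, K = 4, seed = 2)
  expect_equal(cv$mse_pooled, 0, tolerance = 1e-20)
  expect_equal(cv$n_outliers, 0L)
})

test_that("outlier-excluded MSE never exceeds the pooled MSE", {
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n) + c(rep(0, n - 2), 5, -6)  # two gross outliers
    cv <- kfold_validate(data.frame(x = x), y, K = 4, seed = i)
    expect_lte(cv$mse_excl_outliers, cv$mse_pooled)
  }
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(6)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- 0.5 * X$a + rnorm(40)
  a <- kfold_validate(X, y, K = 4, seed = 11)
  b <- kfold_validate(X, y, K = 4, seed = 11)
  expect_identical(a$predictions, b$predictions)
  c2 <- kfold_validate(X, y, K = 4, seed = 12)
  expect_false(identical(a$folds, c2$folds))
})

test_that("cross-validated error is honest: no leakage under the null", {
  set.seed(81)
  n_rep <- 60
  cv_mse <- insample_mse <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 44
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("p", 1:6))))
    y <- rnorm(n)
    m <- stepwise_fit(X, y)
    pred_in <- predict(m, X)
    insample_mse[i] <- mean((y - pred_in)^2)
    cv_mse[i] <- kfold_validate(X, y, K = 4, seed = i)$mse_pooled
  }
  expect_gt(mean(cv_mse), mean(insample_mse))
})

test_that("run_all_models summarizes one model per g score set", {
  coh <- generate_cohort(cohort_config(n_subjects = 98, seed = 91))
  cs <- condition_battery(coh$scores, default_battery())
  gsets <- estimate_all_g(cs)[1:3]
  preds <- morph_predictors(coh$ct, coh$lgi,
                            names(default_ct_effects()),
                            names(default_lgi_effects()))
  suite <- run_all_models(preds, gsets, K = 4, seed = 2)
  expect_equal(nrow(suite$summary), 3)
  expect_identical(suite$summary$combo_id,
                   vapply(gsets, function(g) g$combo_id, character(1),
                          USE.NAMES = FALSE))
  expect_equal(sum(suite$selection_freq$times_selected),
               sum(suite$summary$n_selected))
  expect_true(all(suite$summary$adj_r_squared <= suite$summary$r_squared))

  single <- run_all_models(preds, gsets[1], K = 4, seed = 2)
  expect_equal(single$median_adj_r2, single$summary$adj_r_squared[1])
})

test_that("null predictors yield near-zero median adjusted R-squared", {
  set.seed(101)
  meds <- vapply(1:15, function(i) {
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("p", 1:5))))
    gsets <- list(as_gset(rnorm(n), "g1"), as_gset(rnorm(n), "g2"))
    suite <- run_all_models(X, gsets, K = 4, seed = i)
    suite$median_adj_r2
  }, numeric(1))
  expect_lte(median(meds), 0.05)
})
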