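test_that("glm_partial recovers exact linear relations", {
  g <- rnorm(30)
  out <- glm_partial(2 * g, g)
  expect_equal(out$slope, 2, tolerance = 1e-10)
  expect_equal(out$r, 1, tolerance = 1e-10)
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 40
    Z <- cbind(gender = rbinom(n, 1, 0.5), hand = sample(1:5, n, TRUE))
    g <- rnorm(n) + 0.3 * Z[, 1]
    y <- 0.4 * g + 0.2 * Z[, 2] + rnorm(n)
    fitted <- glm_partial(y, g, Z)

    # oracle: explicit projection on [1, Z], then plain Pearson correlation
    P <- cbind(1, Z)
    H <- P %*% solve(crossprod(P)) %*% t(P)
    ry <- y - H %*% y
    rg <- g - H %*% g
    expect_equal(fitted$r, cor(ry, rg)[1, 1], tolerance = 1e-10)
    expect_equal(fitted$slope, sum(ry * rg) / sum(rg^2), tolerance = 1e-10)
  }
})

test_that("glm_partial flags rank-deficient designs", {
  n <- 20
  g <- rnorm(n)
  expect_error(glm_partial(rnorm(n), g, cbind(a = g)), "rank deficient")
})

test_that("the t statistic is t-distributed under the null", {
  set.seed(77)
  n <- 44
  tstats <- vapply(seq_len(2000), function(i) {
    Z <- cbind(rbinom(n, 1, 0.5), sample(1:5, n, TRUE))
    glm_partial(rnorm(n), rnorm(n), Z)$t
  }, numeric(1))
  ks <- ks.test(tstats, pt, df = n - 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("a single-ROI family has corrected p equal to uncorrected p", {
  set.seed(4)
  mt <- as_mtable(matrix(rnorm(40), 40, 1, dimnames = list(NULL, "r1")))
  g <- as_gset(rnorm(40))
  out <- permutation_fwe(mt, g, n_perm = 300, seed = 2)
  expect_equal(out$p_fwe, out$p_uncorrected)
})

test_that("a perfectly dependent family is not over-penalized", {
  set.seed(5)
  y <- rnorm(44)
  Y <- matrix(y, 44, 25)
  colnames(Y) <- paste0("r", 1:25)
  out <- permutation_fwe(as_mtable(Y), as_gset(rnorm(44)),
                         n_perm = 300, seed = 3)
  expect_equal(out$p_fwe, out$p_uncorrected)
})

test_that("a vacuous threshold flags everything significant", {
  set.seed(6)
  mt <- as_mtable(matrix(rnorm(40 * 5), 40, 5))
  out <- permutation_fwe(mt, as_gset(rnorm(40)), n_perm = 200,
                         alpha = 1, seed = 9)
  expect_true(all(out$significant))
})

test_that("zero-variance ROI columns are excluded with a warning", {
  set.seed(8)
  Y <- cbind(r1 = rnorm(30), r2 = rep(1, 30), r3 = rnorm(30))
  expect_warning(
    out <- permutation_fwe(as_mtable(Y), as_gset(rnorm(30)),
                           n_perm = 200, seed = 1),
    "zero-variance"
  )
  expect_true(is.na(out$p_fwe[out$roi == "r2"]))
  expect_false(out$significant[out$roi == "r2"])
  expect_false(anyNA(out$p_fwe[out$roi != "r2"]))
})

test_that("corrected p is monotone in family size and permutation p is affine-invariant", {
  set.seed(10)
  n <- 40
  Y <- matrix(rnorm(n * 6), n, 6)
  colnames(Y) <- paste0("r", 1:6)
  g <- as_gset(0.5 * Y[, 1] + rnorm(n))
  big <- permutation_fwe(as_mtable(Y), g, n_perm = 400, seed = 12)
  small <- permutation_fwe(as_mtable(Y[, 1:2]), g, n_perm = 400, seed = 12)
  shared <- c("r1", "r2")
  expect_true(all(big$p_fwe[match(shared, big$roi)] >=
                    small$p_fwe[match(shared, small$roi)]))

  # location-scale change of each ROI leaves permutation p untouched
  Y2 <- sweep(sweep(Y, 2, c(2, 3, 0.5, 10, 1, 4), "*"), 2, 1:6, "+")
  colnames(Y2) <- colnames(Y)
  again <- permutation_fwe(as_mtable(Y2), g, n_perm = 400, seed = 12)
  expect_equal(again$p_fwe, big$p_fwe, tolerance = 1e-12)
  expect_equal(again$p_uncorrected, big$p_uncorrected, tolerance = 1e-12)
})

test_that("permutation results are reproducible given the seed", {
  set.seed(20)
  mt <- as_mtable(matrix(rnorm(35 * 4), 35, 4))
  g <- as_gset(rnorm(35))
  a <- permutation_fwe(mt, g, n_perm = 300, seed = 99)
  b <- permutation_fwe(mt, g, n_perm = 300, seed = 99)
  expect_identical(a, b)
  c2 <- permutation_fwe(mt, g, n_perm = 300, seed = 100)
  expect_false(identical(a$p_fwe, c2$p_fwe))
})

test_that("true effects are detected and the sign convention matches morphometry", {
  coh <- generate_cohort(cohort_config(n_subjects = 98, seed = 35))
  cs <- condition_battery(coh$scores, default_battery())
  gsets <- estimate_all_g(cs)[1:4]
  sm <- build_significance_matrix(coh$ct, gsets, n_perm = 400, seed = 7)
  expect_equal(dim(sm$significance), c(25, 4))
  expect_identical(rownames(sm$significance), roi_labels()$roi)
  # strongest CT effect: negative partial r, significant for these g sets
  itg <- sm$results[sm$results$roi == "inferior_temporal_gyrus", ]
  expect_true(all(itg$r < 0))
  expect_true(any(itg$significant))
  lg <- build_significance_matrix(coh$lgi, gsets[1], n_perm = 400, seed = 8)
  vpc <- lg$results[lg$results$roi == "ventral_posterior_cingulate", ]
  expect_true(all(vpc$r > 0))
})

test_that("family-split correction equals per-family runs", {
  coh <- generate_cohort(cohort_config(n_subjects = 44, seed = 45))
  cs <- condition_battery(coh$scores, default_battery())
  gsets <- estimate_all_g(cs)[1]
  labs <- roi_labels()
  fam <- stats::setNames(labs$network, labs$roi)
  split_run <- build_significance_matrix(coh$ct, gsets, n_perm = 300,
                                         seed = 5, families = fam)
  dmn_cols <- c("subject_id", "gender", "handedness",
                labs$roi[labs$network == "DMN"])
  dmn_only <- build_significance_matrix(coh$ct[, dmn_cols], gsets,
                                        n_perm = 300, seed = 5)
  shared <- labs$roi[labs$network == "DMN"]
  expect_equal(split_run$results$p_fwe[match(shared, split_run$results$roi)],
               dmn_only$results$p_fwe[match(shared, dmn_only$results$roi)],
               tolerance = 1e-12)
})
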