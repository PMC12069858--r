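test_that("combination enumeration is the full Cartesian product in order", {
  combos <- enumerate_combinations(default_battery())
  expect_equal(nrow(combos), 24)
  expect_equal(anyDuplicated(combos$combo_id), 0)
  # lexicographic: first domain varies slowest, last fastest
  expect_equal(combos$executive,
               rep(c("trail_making", "symbol_digit", "stroop"), each = 8))
  expect_equal(combos$math_logic[1:2], c("math_puzzles", "logical_reasoning"))

  one <- battery(list(a = "t1"))
  expect_equal(nrow(enumerate_combinations(one)), 1)

  two <- plain_battery()
  c22 <- enumerate_combinations(two)
  expect_equal(nrow(c22), 4)
  expect_equal(nrow(dplyr::distinct(c22)), 4)
})

test_that("combination count equals the product of domain sizes", {
  set.seed(11)
  for (rep in 1:10) {
    sizes <- sample(1:4, sample(2:4, 1), replace = TRUE)
    doms <- lapply(seq_along(sizes), function(i) {
      paste0("d", i, "_t", seq_len(sizes[i]))
    })
    names(doms) <- paste0("d", seq_along(sizes))
    combos <- enumerate_combinations(battery(doms))
    expect_equal(nrow(combos), prod(sizes))
    expect_equal(anyDuplicated(combos$combo_id), 0)
  }
})

test_that("four exact copies of one vector give unit loadings and that vector back", {
  set.seed(2)
  v <- rnorm(40)
  cs <- as_conditioned(data.frame(x1 = v, x2 = v, x3 = v, x4 = v),
                       four_test_battery())
  gs <- fit_single_factor(cs, c("x1", "x2", "x3", "x4"))
  expect_equal(unname(gs$loadings), rep(1, 4), tolerance = 1e-3)
  expect_equal(gs$scores, as.numeric(scale(v)), tolerance = 1e-6)
  expect_true(gs$heywood)
})

test_that("loadings of an exact rank-1-plus-diagonal correlation matrix are recovered", {
  lambda <- c(0.8, 0.7, 0.6, 0.5)
  sigma <- tcrossprod(lambda) + diag(1 - lambda^2)
  colnames(sigma) <- rownames(sigma) <- paste0("x", 1:4)
  X <- data_with_exact_cor(200, sigma, seed = 6)
  cs <- as_conditioned(as.data.frame(X), four_test_battery())
  gs <- fit_single_factor(cs, paste0("x", 1:4))
  expect_equal(unname(gs$loadings), lambda, tolerance = 1e-3)
  expect_equal(gs$method, "ml")
})

test_that("factor scores track latent g under the generative model", {
  cfg <- cohort_config(
    n_subjects = 500, battery = four_test_battery(),
    loading_range = c(0.7, 0.7), domain_noise_sd = 0,
    test_noise_sd = sqrt(1 - 0.49),
    ct_effects = numeric(0), lgi_effects = numeric(0),
    skewed_tests = character(0), seed = 41
  )
  coh <- generate_cohort(cfg)
  cs <- condition_battery(coh$scores, cfg$battery)
  gs <- fit_single_factor(cs, paste0("x", 1:4))
  expect_gte(cor(gs$scores, coh$latent_g), 0.85)
})

test_that("factor scores are invariant to the order tests are listed in", {
  coh <- generate_cohort(cohort_config(n_subjects = 80, seed = 19))
  cs <- condition_battery(coh$scores, default_battery())
  a <- fit_single_factor(cs, c("stroop", "word_puzzles", "fas_test",
                               "math_puzzles"))
  b <- fit_single_factor(cs, c("math_puzzles", "fas_test", "word_puzzles",
                               "stroop"))
  expect_equal(a$scores, b$scores, tolerance = 1e-8)
  expect_identical(a$combo_id, b$combo_id)
})

test_that("sign alignment makes g correlate positively with performance", {
  set.seed(23)
  coh <- generate_cohort(cohort_config(n_subjects = 120, seed = 23))
  cs <- condition_battery(coh$scores, default_battery())
  combo <- c("stroop", "comprehension", "fas_test", "math_puzzles")
  gs <- fit_single_factor(cs, combo)
  expect_gt(sum(gs$loadings), 0)
  # reversing a single indicator flips that loading but, after alignment,
  # leaves the factor scores unchanged -- negated score sets cannot arise
  neg <- cs
  neg$scores$stroop <- -neg$scores$stroop
  gneg <- fit_single_factor(neg, combo)
  expect_lt(gneg$loadings[["stroop"]], 0)
  expect_gt(sum(gneg$loadings), 0)
  expect_equal(cor(gs$scores, gneg$scores), 1, tolerance = 1e-6)
})

test_that("equal-loading generator yields near-equal loadings", {
  cfg <- cohort_config(
    n_subjects = 2000, battery = four_test_battery(),
    loading_range = c(0.75, 0.75), domain_noise_sd = 0,
    test_noise_sd = sqrt(1 - 0.75^2),
    ct_effects = numeric(0), lgi_effects = numeric(0),
    skewed_tests = character(0), seed = 51
  )
  coh <- generate_cohort(cfg)
  cs <- condition_battery(coh$scores, cfg$battery)
  gs <- fit_single_factor(cs, paste0("x", 1:4))
  expect_lt(diff(range(gs$loadings)), 0.08)
})

test_that("estimate_all_g maps the enumeration deterministically", {
  coh <- generate_cohort(cohort_config(n_subjects = 44, seed = 3))
  cs <- condition_battery(coh$scores, default_battery())
  gsets <- estimate_all_g(cs)
  expect_length(gsets, 24)
  expect_identical(names(gsets), enumerate_combinations(default_battery())$combo_id)
  again <- estimate_all_g(cs)
  expect_equal(gscore_matrix(gsets), gscore_matrix(again), tolerance = 1e-12)

  singleton <- battery(list(a = "word_puzzles", b = "fas_test",
                            c = "stroop", d = "math_puzzles"))
  cs1 <- structure(cs, class = "conditioned_scores")
  cs1$battery <- singleton
  expect_length(estimate_all_g(cs1, singleton), 1)
})

test_that("manifold summary reports off-diagonal correlations", {
  v <- rnorm(30)
  sets <- list(as_gset(v, "a"), as_gset(v, "b"), as_gset(v, "c"))
  ms <- manifold_summary(sets)
  expect_equal(ms$median_r, 1, tolerance = 1e-12)
  expect_equal(ms$min_r, 1, tolerance = 1e-12)
  expect_true(isSymmetric(ms$cor_matrix))
  expect_equal(unname(diag(ms$cor_matrix)), rep(1, 3))
  expect_error(manifold_summary(sets[1]), "at least two")
  bad <- as_gset(rnorm(31), "d")
  expect_error(manifold_summary(list(sets[[1]], bad)), "mismatched")
})

test_that("positive manifold holds for the default generator", {
  coh <- generate_cohort(cohort_config(n_subjects = 98, seed = 29))
  cs <- condition_battery(coh$scores, default_battery())
  ms <- manifold_summary(estimate_all_g(cs))
  expect_gt(ms$min_r, 0)
  expect_gt(ms$median_r, 0.7)
})
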