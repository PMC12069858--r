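# Shared fixtures: small batteries and cohort configurations used across
# the test files. Everything is generated in code; no stored data.

# A two-domain battery with no timed tests, handy for degenerate checks.
plain_battery <- function() {
  battery(domains = list(
    a = c("t1", "t2"),
    b = c("t3", "t4")
  ))
}

# Four-test battery, one domain each, no timing/skew: the minimal shape for
# a single-factor fit.
four_test_battery <- function() {
  battery(domains = list(d1 = "x1", d2 = "x2", d3 = "x3", d4 = "x4"))
}

# Noise-free degenerate configuration: every test column must equal the
# latent g exactly (before any exponentiation).
noise_free_config <- function(n = 30, seed = 99) {
  cohort_config(
    n_subjects = n, battery = plain_battery(),
    loading_range = c(1, 1), domain_noise_sd = 0, test_noise_sd = 0,
    ct_effects = numeric(0), lgi_effects = numeric(0),
    covariate_effects = stats::setNames(
      lapply(roi_labels()$roi, function(r) c(0, 0)), roi_labels()$roi),
    skewed_tests = character(0), seed = seed
  )
}

# Build a conditioned_scores object directly from a numeric matrix whose
# columns are already standardized test scores (bypasses conditioning).
as_conditioned <- function(X, battery) {
  X <- as.data.frame(scale(X))
  tab <- tibble::as_tibble(cbind(
    subject_id = sprintf("S%03d", seq_len(nrow(X))), X))
  for (j in names(X)) tab[[j]] <- as.numeric(scale(tab[[j]]))
  structure(
    list(scores = tab,
         provenance = tibble::tibble(test = names(X)),
         alpha = 0.05, battery = battery),
    class = "conditioned_scores"
  )
}

# Generate an n x p data matrix whose *sample* correlation matrix equals
# `sigma` exactly: whiten standardized noise, then color by chol(sigma).
data_with_exact_cor <- function(n, sigma, seed = 1) {
  p <- ncol(sigma)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  S <- stats::cov(X)
  X <- X %*% solve(chol(S))           # whitened: sample cov = I
  X <- X %*% chol(sigma)
  colnames(X) <- colnames(sigma)
  X
}

# Morphometry-style tibble from a matrix of ROI values plus covariates.
as_mtable <- function(Y, gender = NULL, handedness = NULL, measure = "CT") {
  n <- nrow(Y)
  if (is.null(gender)) gender <- rep_len(c(0L, 1L), n)
  if (is.null(handedness)) handedness <- rep_len(c(5L, 5L, 5L, 4L, 1L), n)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("roi_", seq_len(ncol(Y)))
  tab <- tibble::as_tibble(as.data.frame(Y))
  tab <- tibble::add_column(tab,
    subject_id = sprintf("S%03d", seq_len(n)),
    gender = gender, handedness = handedness, .before = 1)
  attr(tab, "measure") <- measure
  tab
}

# Wrap a numeric vector as a g_score_set aligned to n subjects.
as_gset <- function(scores, id = "gset") {
  structure(
    list(combo_id = id, tests = character(0),
         loadings = numeric(0), uniquenesses = numeric(0),
         scores = as.numeric(scale(scores)),
         subject_id = sprintf("S%03d", seq_along(scores)),
         method = "manual", heywood = FALSE),
    class = "g_score_set"
  )
}
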