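#' Enumerate all one-test-per-domain combinations
#'
#' Forms the full Cartesian product of the battery's domains, selecting
#' exactly one test from each domain. The order is deterministic and
#' lexicographic in (domain order, within-domain test order), and the
#' number of combinations is the product of the domain sizes (24 for the
#' reference 3/2/2/2 battery).
#'
#' @param battery A [battery()] object.
#' @return A tibble with one row per combination: one column per domain
#'   holding the selected test, plus `combo_id`, a `"domain:test"` token
#'   list joined by `"+"`.
#' @examples
#' nrow(enumerate_combinations(default_battery()))
#' @export
enumerate_combinations <- function(battery) {
  stopifnot(inherits(battery, "battery"))
  if (any(lengths(battery$domains) < 1L)) {
    stop("every domain needs at least one test", call. = FALSE)
  }
  grid <- tidyr::expand_grid(!!!battery$domains)
  ids <- purrr::pmap_chr(grid, function(...) {
    paste(paste(names(grid), c(...), sep = ":"), collapse = "+")
  })
  dplyr::mutate(grid, combo_id = ids)
}

# Least-squares (minres-style) single-factor fit of a correlation matrix:
# minimizes the off-diagonal residuals of R - L L'. Used when the ML route
# fails, e.g. for (near-)singular correlation matrices.
minres_single_factor <- function(R) {
  p <- ncol(R)
  off <- upper.tri(R)
  objective <- function(l) sum((R[off] - tcrossprod(l)[off])^2)
  e1 <- eigen(R, symmetric = TRUE)
  start <- e1$vectors[, 1] * sqrt(max(e1$values[1], 1e-8))
  start <- pmin(pmax(start, -0.999), 0.999)
  fit <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = rep(-1, p), upper = rep(1, p),
                      control = list(maxit = 500))
  fit$par
}

#' Fit a single unrotated common factor to a test combination
#'
#' Extracts one common factor from the correlation matrix of the selected
#' conditioned test scores by maximum likelihood (the classical unrotated
#' factor analysis, with uniquenesses floored at 0.005 so Heywood cases are
#' handled by clamping), falling back to an unweighted least-squares
#' (minres) fit when the ML fit cannot run, e.g. for a singular correlation
#' matrix. Factor scores are computed by the regression (Thomson) method
#' from the model-implied correlation matrix, sign-aligned so the loading
#' sum is positive (g correlates positively with performance), and
#' re-standardized.
#'
#' @param conditioned A [condition_battery()] result.
#' @param combo Character vector of test names, one per battery domain (a
#'   row of [enumerate_combinations()] works via its domain columns).
#' @return An object of class `g_score_set`: list with `combo_id`, `tests`,
#'   `loadings`, `uniquenesses`, `scores` (standardized, one per subject),
#'   `subject_id`, `method` (`"ml"` or `"minres"`), `heywood` flag.
#' @export
fit_single_factor <- function(conditioned, combo) {
  stopifnot(inherits(conditioned, "conditioned_scores"))
  bat <- conditioned$battery
  tests <- combo_tests(combo, bat)
  tab <- conditioned$scores
  n <- nrow(tab)
  if (n < 4L) stop("need at least 4 subjects for a factor fit", call. = FALSE)
  X <- as.matrix(tab[, tests])
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("zero-variance test column among: ",
         paste(tests, collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(X)

  method <- "ml"
  L <- tryCatch({
    fa <- stats::factanal(covmat = R, factors = 1, rotation = "none",
                          n.obs = n)
    as.numeric(fa$loadings)
  }, error = function(e) NULL)
  if (is.null(L)) {
    method <- "minres"
    L <- minres_single_factor(R)
  }
  psi <- pmax(1 - L^2, 0.005)
  heywood <- any(1 - L^2 < 0.005)

  # Thomson regression scores from the model-implied correlation, defined
  # even when the sample correlation matrix is singular.
  sigma_model <- tcrossprod(L) + diag(psi)
  w <- solve(sigma_model, L)
  Z <- scale(X)
  f <- as.numeric(Z %*% w)

  s <- sum(L)
  flip <- if (s != 0) s < 0 else L[1] < 0
  if (flip) {
    L <- -L
    f <- -f
  }
  f <- zstd(f, "factor scores")

  structure(
    list(
      combo_id = combo_id_for(tests, bat),
      tests = tests,
      loadings = stats::setNames(L, tests),
      uniquenesses = stats::setNames(psi, tests),
      scores = f,
      subject_id = tab$subject_id,
      method = method,
      heywood = heywood
    ),
    class = "g_score_set"
  )
}

# Resolve a combination argument (character vector or one-row enumeration
# tibble) to an ordered one-test-per-domain character vector.
combo_tests <- function(combo, battery) {
  if (is.data.frame(combo)) {
    stopifnot(nrow(combo) == 1L)
    combo <- unlist(combo[, names(battery$domains)], use.names = FALSE)
  }
  combo <- as.character(combo)
  doms <- names(battery$domains)
  if (length(combo) != length(doms)) {
    stop("a combination must select exactly one test per domain",
         call. = FALSE)
  }
  picked <- character(length(doms))
  for (i in seq_along(doms)) {
    hit <- intersect(combo, battery$domains[[doms[i]]])
    if (length(hit) != 1L) {
      stop("combination must contain exactly one test from domain `",
           doms[i], "`", call. = FALSE)
    }
    picked[i] <- hit
  }
  picked
}

combo_id_for <- function(tests, battery) {
  doms <- names(battery$domains)
  paste(paste(doms, tests, sep = ":"), collapse = "+")
}

#' @export
print.g_score_set <- function(x, ...) {
  cat("<g_score_set>", x$combo_id, "\n  loadings:",
      paste(sprintf("%s=%.3f", names(x$loadings), x$loadings),
            collapse = ", "),
      "\n  method:", x$method,
      if (x$heywood) "(Heywood clamp applied)" else "", "\n")
  invisible(x)
}

#' Estimate g for every test combination
#'
#' Maps [fit_single_factor()] over [enumerate_combinations()], producing
#' one set of factor scores (one parallel g estimate) per one-test-per-
#' domain combination, in enumeration order.
#'
#' @inheritParams fit_single_factor
#' @param battery A [battery()] object; defaults to the battery recorded in
#'   `conditioned`.
#' @return A list of `g_score_set` objects, named by `combo_id`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 60, seed = 3))
#' cs <- condition_battery(coh$scores, default_battery())
#' gsets <- estimate_all_g(cs)
#' length(gsets)
#' @export
estimate_all_g <- function(conditioned, battery = conditioned$battery) {
  combos <- enumerate_combinations(battery)
  doms <- names(battery$domains)
  gsets <- purrr::map(seq_len(nrow(combos)), function(i) {
    tests <- unlist(combos[i, doms], use.names = FALSE)
    tryCatch(
      fit_single_factor(conditioned, tests),
      error = function(e) {
        stop("factor fit failed for combination `", combos$combo_id[i],
             "`: ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  stats::setNames(gsets, combos$combo_id)
}

#' Matrix of g scores across score sets
#'
#' @param gsets List of `g_score_set` objects with identical subjects.
#' @return Numeric matrix, subjects x score sets, columns named by
#'   `combo_id`.
#' @export
gscore_matrix <- function(gsets) {
  stopifnot(length(gsets) >= 1L)
  ids <- gsets[[1]]$subject_id
  for (gs in gsets) {
    if (!identical(gs$subject_id, ids)) {
      stop("g score sets have mismatched subject orderings", call. = FALSE)
    }
  }
  m <- vapply(gsets, function(gs) gs$scores, numeric(length(ids)))
  colnames(m) <- vapply(gsets, function(gs) gs$combo_id, character(1))
  rownames(m) <- ids
  m
}

#' Positive-manifold summary of parallel g estimates
#'
#' Computes the pairwise Pearson correlation matrix across all g score
#' sets and summarizes its strictly off-diagonal entries. Under the
#' positive-manifold phenomenon the parallel g estimates derived from
#' different test combinations should be mutually highly positively
#' correlated.
#'
#' @param gsets List of `g_score_set` objects (>= 2) over the same
#'   subjects, as from [estimate_all_g()].
#' @return An object of class `manifold_summary`: list with `cor_matrix`,
#'   `median_r`, `min_r`, `max_r`, `n_sets`.
#' @export
manifold_summary <- function(gsets) {
  if (length(gsets) < 2L) {
    stop("need at least two g score sets for a manifold summary",
         call. = FALSE)
  }
  m <- gscore_matrix(gsets)
  cm <- stats::cor(m)
  off <- cm[upper.tri(cm)]
  structure(
    list(cor_matrix = cm, median_r = stats::median(off),
         min_r = min(off), max_r = max(off), n_sets = ncol(cm)),
    class = "manifold_summary"
  )
}

#' @export
print.manifold_summary <- function(x, ...) {
  cat(sprintf(
    "<manifold_summary> %d g score sets; off-diagonal Pearson r: median %.3f (range %.3f-%.3f)\n",
    x$n_sets, x$median_r, x$min_r, x$max_r))
  invisible(x)
}
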