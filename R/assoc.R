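#' Covariate-adjusted association of one outcome with g
#'
#' Least-squares fit of `y` on `[1, g, covariates]`, returning the slope on
#' g, the partial Pearson correlation of `y` and `g` given the covariates
#' (sign matching the slope), and the t statistic of the slope.
#'
#' @param y Numeric outcome vector (e.g. one ROI's morphometry values).
#' @param g Numeric predictor of interest (a g score vector).
#' @param covariates Optional numeric matrix/data frame of nuisance
#'   covariates (e.g. gender, handedness), same number of rows.
#' @return A list with `slope`, `r` (partial correlation) and `t`.
#' @examples
#' glm_partial(1:10 * 2, 1:10)$slope
#' @export
glm_partial <- function(y, g, covariates = NULL) {
  n <- length(y)
  if (length(g) != n) stop("`y` and `g` lengths differ", call. = FALSE)
  Z <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  X <- cbind(Z, g = g)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(X)
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  rss <- sum(res^2)
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(rss / df * xtxi[ncol(X), ncol(X)])
  tval <- if (se > 0) beta[["g"]] / se else sign(beta[["g"]]) * Inf
  r <- if (is.finite(tval)) tval / sqrt(tval^2 + df) else sign(tval)
  list(slope = unname(beta[["g"]]), r = r, t = unname(tval))
}

# Partial-regression statistics of every column of Y on g given Z1 (which
# must include the intercept): slopes, t statistics and partial r, computed
# via Frisch-Waugh so the whole ROI family is handled in one matrix pass.
partial_stats <- function(Yres, g_res, df) {
  d <- sum(g_res^2)
  cross <- as.numeric(crossprod(Yres, g_res))
  beta <- cross / d
  rss <- colSums(Yres^2) - beta^2 * d
  rss <- pmax(rss, 0)
  tval <- beta * sqrt(d) / sqrt(rss / df)
  list(slope = beta, t = tval, r = tval / sqrt(tval^2 + df))
}

#' Permutation family-wise error corrected association of ROIs with g
#'
#' For every ROI column in the morphometry table, fits the covariate-
#' adjusted linear model of ROI value on the g scores and assesses
#' significance by Freedman-Lane permutation: the covariate-residualized g
#' vector is permuted, re-residualized on the covariates, and the maximum
#' absolute t statistic across the ROI family per permutation builds the
#' family-wise null. Corrected p-values use add-one smoothing,
#' `(b + 1) / (n_perm + 1)`, and are therefore never zero.
#'
#' @param mtable Morphometry tibble: `subject_id`, covariate columns
#'   (`gender`, `handedness` by default), then one column per ROI.
#' @param gset A `g_score_set` (or a bare numeric vector aligned to the
#'   table's subjects).
#' @param n_perm Number of permutations (>= 100; default 5000).
#' @param alpha Significance level applied to the corrected p (default
#'   0.05).
#' @param seed Integer seed making the permutation draw reproducible.
#' @param covariates Names of the covariate columns to adjust for.
#' @return A tibble with one row per ROI: `roi`, `slope`, `r`, `t`,
#'   `p_uncorrected`, `p_fwe`, `significant`. Zero-variance ROI columns are
#'   flagged with a warning and returned with `NA` statistics and
#'   `significant = FALSE`.
#' @export
permutation_fwe <- function(mtable, gset, n_perm = 5000, alpha = 0.05,
                            seed = 1L,
                            covariates = c("gender", "handedness")) {
  if (n_perm < 100L) stop("need at least 100 permutations", call. = FALSE)
  if (1 / (n_perm + 1) > alpha) {
    warning("n_perm too small to resolve alpha = ", alpha, call. = FALSE)
  }
  mtable <- tibble::as_tibble(mtable)
  g <- if (inherits(gset, "g_score_set")) {
    if (!identical(gset$subject_id, mtable$subject_id)) {
      stop("subjects of the g score set and morphometry table do not align",
           call. = FALSE)
    }
    gset$scores
  } else {
    as.numeric(gset)
  }
  n <- nrow(mtable)
  if (length(g) != n) stop("g scores do not match table rows", call. = FALSE)

  roi_cols <- setdiff(names(mtable), c("subject_id", covariates))
  Y <- as.matrix(mtable[, roi_cols, drop = FALSE])
  sds <- apply(Y, 2, stats::sd)
  dead <- roi_cols[sds == 0]
  if (length(dead)) {
    warning("excluding zero-variance ROI column(s): ",
            paste(dead, collapse = ", "), call. = FALSE)
  }
  live <- setdiff(roi_cols, dead)
  out <- tibble::tibble(
    roi = roi_cols, slope = NA_real_, r = NA_real_, t = NA_real_,
    p_uncorrected = NA_real_, p_fwe = NA_real_, significant = FALSE
  )
  if (!length(live)) return(out)

  Yl <- Y[, live, drop = FALSE]
  Z1 <- cbind(1, as.matrix(mtable[, intersect(covariates, names(mtable))]))
  qz <- qr(Z1)
  df <- n - ncol(Z1) - 1L
  g_res <- qr.resid(qz, g)
  Yres <- qr.resid(qz, Yl)
  obs <- partial_stats(Yres, g_res, df)

  perm_t <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
    P <- matrix(g_res[idx], n, n_perm)
    Pr <- qr.resid(qz, P)
    d_p <- colSums(Pr^2)
    cross <- crossprod(Yres, Pr)                       # ROIs x perms
    rss0 <- colSums(Yres^2)
    beta_p <- sweep(cross, 2, d_p, "/")
    rss_p <- pmax(rss0 - sweep(beta_p^2, 2, d_p, "*"), 0)
    abs(sweep(beta_p, 2, sqrt(d_p), "*") / sqrt(rss_p / df))
  })
  max_t <- apply(perm_t, 2, max)

  abs_obs <- abs(obs$t)
  p_fwe <- vapply(abs_obs, function(t0) (1 + sum(max_t >= t0)) / (n_perm + 1),
                  numeric(1))
  p_unc <- vapply(seq_along(live), function(j) {
    (1 + sum(perm_t[j, ] >= abs_obs[j])) / (n_perm + 1)
  }, numeric(1))

  ix <- match(live, out$roi)
  out$slope[ix] <- obs$slope
  out$r[ix] <- obs$r
  out$t[ix] <- obs$t
  out$p_uncorrected[ix] <- p_unc
  out$p_fwe[ix] <- p_fwe
  # alpha >= 1 is a vacuous threshold: every testable ROI passes
  out$significant[ix] <- if (alpha >= 1) TRUE else p_fwe < alpha
  out
}

#' Significance matrix of every ROI against every g score set
#'
#' Runs the permutation family-wise error analysis of [permutation_fwe()]
#' once per g score set and collates the results into an ROI x g-set
#' significance matrix plus the full association statistics. ROI families
#' (e.g. the DMN and TPN node sets) can be corrected separately.
#'
#' @inheritParams permutation_fwe
#' @param gsets List of `g_score_set` objects, as from [estimate_all_g()].
#' @param families Optional named character vector mapping ROI labels to a
#'   family label; the max-statistic correction is then applied within each
#'   family separately. `NULL` treats all ROIs as one family.
#' @return An object of class `roi_association`: list with `significance`
#'   (logical ROI x g-set matrix), `results` (tibble of per-ROI, per-g-set
#'   statistics with a `combo_id` column), `measure`, `alpha`, `n_perm`,
#'   `seed`.
#' @export
build_significance_matrix <- function(mtable, gsets, n_perm = 5000,
                                      alpha = 0.05, seed = 1L,
                                      covariates = c("gender", "handedness"),
                                      families = NULL) {
  mtable <- tibble::as_tibble(mtable)
  roi_cols <- setdiff(names(mtable), c("subject_id", covariates))
  fam <- if (is.null(families)) {
    stats::setNames(rep("all", length(roi_cols)), roi_cols)
  } else {
    missing_fam <- setdiff(roi_cols, names(families))
    if (length(missing_fam)) {
      stop("no family assignment for ROI(s): ",
           paste(missing_fam, collapse = ", "), call. = FALSE)
    }
    families[roi_cols]
  }

  combo_ids <- vapply(seq_along(gsets), function(k) {
    gs <- gsets[[k]]
    if (inherits(gs, "g_score_set")) gs$combo_id else paste0("gset_", k)
  }, character(1))

  per_set <- purrr::map(seq_along(gsets), function(k) {
    gs <- gsets[[k]]
    per_fam <- purrr::map_dfr(unique(fam), function(f) {
      cols <- c("subject_id", intersect(covariates, names(mtable)),
                roi_cols[fam == f])
      permutation_fwe(mtable[, cols], gs, n_perm = n_perm, alpha = alpha,
                      seed = seed + k, covariates = covariates)
    })
    per_fam$combo_id <- combo_ids[k]
    per_fam[match(roi_cols, per_fam$roi), ]
  })
  results <- dplyr::bind_rows(per_set)

  sig <- matrix(FALSE, length(roi_cols), length(gsets),
                dimnames = list(roi_cols, combo_ids))
  for (j in seq_along(gsets)) {
    sig[, j] <- per_set[[j]]$significant
  }

  structure(
    list(significance = sig, results = tibble::as_tibble(results),
         measure = attr(mtable, "measure"), alpha = alpha,
         n_perm = n_perm, seed = seed, families = fam),
    class = "roi_association"
  )
}

#' @export
print.roi_association <- function(x, ...) {
  cat("<roi_association>", if (!is.null(x$measure)) x$measure else "",
      nrow(x$significance), "ROIs x", ncol(x$significance),
      "g score sets; alpha =", x$alpha, ",", x$n_perm, "permutations\n")
  invisible(x)
}
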