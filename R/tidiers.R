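#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted g-estimation model
#'
#' @param x A `g_estimation_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy g_estimation_model
#' @export
tidy.g_estimation_model <- function(x, ...) {
  terms <- c("(Intercept)", x$selected)
  tibble::tibble(
    term = terms,
    estimate = unname(coef(x)),
    std.error = unname(x$std_errors[terms]),
    statistic = unname(x$t_values[terms]),
    p.value = unname(x$p_values[terms])
  )
}

#' @rdname tidy.g_estimation_model
#' @return For `glance()`: one-row tibble with `r.squared`,
#'   `adj.r.squared`, `sigma`, `df.residual`, `nobs`, `n.selected`.
#' @method glance g_estimation_model
#' @export
glance.g_estimation_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    sigma = x$residual_sd, df.residual = x$n - length(x$selected) - 1L,
    nobs = x$n, n.selected = length(x$selected)
  )
}

#' Tidy cross-validation results
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return For `tidy()`: the per-subject prediction tibble; for
#'   `glance()`: a one-row summary with the pooled and outlier-excluded
#'   MSE.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    K = x$K, nobs = nrow(x$predictions), mse = x$mse_pooled,
    mse.excl.outliers = x$mse_excl_outliers, n.outliers = x$n_outliers
  )
}

#' Tidy a positive-manifold summary
#'
#' @param x A `manifold_summary`.
#' @param ... Unused.
#' @return For `tidy()`: long tibble of the strictly off-diagonal pairwise
#'   correlations (`set1`, `set2`, `r`); for `glance()`: `n.sets`,
#'   `median.r`, `min.r`, `max.r`.
#' @method tidy manifold_summary
#' @export
tidy.manifold_summary <- function(x, ...) {
  cm <- x$cor_matrix
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    set1 = rownames(cm)[idx[, 1]],
    set2 = colnames(cm)[idx[, 2]],
    r = cm[idx]
  )
}

#' @rdname tidy.manifold_summary
#' @method glance manifold_summary
#' @export
glance.manifold_summary <- function(x, ...) {
  tibble::tibble(n.sets = x$n_sets, median.r = x$median_r,
                 min.r = x$min_r, max.r = x$max_r)
}

#' Tidy a consensus report
#'
#' @param x A `consensus_report`.
#' @param ... Unused.
#' @return For `tidy()`: the per-ROI tibble (counts, threshold, accepted,
#'   near-miss, direction); for `glance()`: `K`, `threshold`,
#'   `n.accepted`, `n.near.miss`.
#' @method tidy consensus_report
#' @export
tidy.consensus_report <- function(x, ...) x$roi

#' @rdname tidy.consensus_report
#' @method glance consensus_report
#' @export
glance.consensus_report <- function(x, ...) {
  tibble::tibble(
    K = x$K, threshold = x$threshold,
    n.accepted = sum(x$roi$accepted),
    n.near.miss = sum(x$roi$near_miss)
  )
}

#' Tidy an ROI association scan
#'
#' @param x A `roi_association`.
#' @param ... Unused.
#' @return For `tidy()`: the per-(ROI, g-set) statistics tibble; for
#'   `glance()`: settings and the count of significant cells.
#' @method tidy roi_association
#' @export
tidy.roi_association <- function(x, ...) x$results

#' @rdname tidy.roi_association
#' @method glance roi_association
#' @export
glance.roi_association <- function(x, ...) {
  tibble::tibble(
    measure = if (is.null(x$measure)) NA_character_ else x$measure,
    n.rois = nrow(x$significance), n.sets = ncol(x$significance),
    alpha = x$alpha, n.perm = x$n_perm,
    n.significant = sum(x$significance)
  )
}

#' Tidy a g score set
#'
#' @param x A `g_score_set`.
#' @param ... Unused.
#' @return Tibble with `test`, `loading`, `uniqueness`.
#' @method tidy g_score_set
#' @export
tidy.g_score_set <- function(x, ...) {
  tibble::tibble(test = x$tests,
                 loading = unname(x$loadings),
                 uniqueness = unname(x$uniquenesses))
}

#' Tidy a suite of g-estimation models
#'
#' @param x A `g_model_suite`.
#' @param ... Unused.
#' @return For `tidy()`: the per-model summary tibble; for `glance()`: the
#'   across-model medians and ranges.
#' @method tidy g_model_suite
#' @export
tidy.g_model_suite <- function(x, ...) x$summary

#' @rdname tidy.g_model_suite
#' @method glance g_model_suite
#' @export
glance.g_model_suite <- function(x, ...) {
  tibble::tibble(
    n.models = nrow(x$summary),
    median.adj.r.squared = x$median_adj_r2,
    min.adj.r.squared = x$range_adj_r2[1],
    max.adj.r.squared = x$range_adj_r2[2],
    median.mse = stats::median(x$summary$mse_pooled),
    K = x$K
  )
}
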