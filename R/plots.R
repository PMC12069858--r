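#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of pairwise g-set correlations
#'
#' Visualizes the positive manifold: the Pearson correlation between every
#' pair of parallel g estimates.
#'
#' @param object A `manifold_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot manifold_summary
#' @export
autoplot.manifold_summary <- function(object, ...) {
  cm <- object$cor_matrix
  df <- tidyr::expand_grid(set1 = rownames(cm), set2 = colnames(cm))
  df$r <- as.vector(t(cm))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$set2, colnames(cm)),
    y = factor(.data$set1, rev(rownames(cm))), fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), midpoint = 0) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "Pearson r",
      title = sprintf("Positive manifold: median r = %.2f (%.2f-%.2f)",
                      object$median_r, object$min_r, object$max_r)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Consensus vote counts per ROI
#'
#' Bar chart of the number of g score sets each ROI was significant in,
#' with the majority-vote acceptance threshold marked.
#'
#' @param object A `consensus_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_report
#' @export
autoplot.consensus_report <- function(object, ...) {
  df <- object$roi
  df$roi <- factor(df$roi, df$roi[order(df$n_significant)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_significant, y = .data$roi,
                                   fill = .data$accepted)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$threshold - 0.5,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(
      x = sprintf("significant g score sets (of %d)", object$K),
      y = NULL, fill = "accepted",
      title = sprintf("Consensus vote (threshold %d/%d)%s",
                      object$threshold, object$K,
                      if (!is.null(object$measure))
                        paste0(" - ", object$measure) else "")) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed g from cross-validation
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(
      x = "observed g", y = "predicted g",
      title = sprintf("%d-fold CV: MSE %.3f (%.3f excl. outliers)",
                      object$K, object$mse_pooled,
                      object$mse_excl_outliers)) +
    ggplot2::theme_minimal()
}

#' Partial correlations of ROIs with g across score sets
#'
#' One box per ROI over the covariate-adjusted partial correlations with
#' each of the parallel g estimates, coloured by whether the ROI passed
#' the consensus vote (when a report is supplied).
#'
#' @param object A `roi_association`.
#' @param consensus Optional matching `consensus_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roi_association
#' @export
autoplot.roi_association <- function(object, consensus = NULL, ...) {
  df <- object$results[!is.na(object$results$r), ]
  if (!is.null(consensus)) {
    df <- dplyr::left_join(df, consensus$roi[, c("roi", "accepted")],
                           by = "roi")
  } else {
    df$accepted <- NA
  }
  df$roi <- factor(df$roi, rev(rownames(object$significance)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$roi,
                                   colour = .data$accepted)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = "partial Pearson r with g", y = NULL,
      title = paste0("ROI-g association",
                     if (!is.null(object$measure))
                       paste0(" (", object$measure, ")") else "")) +
    ggplot2::theme_minimal()
}
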