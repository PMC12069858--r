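#' Majority-vote consensus threshold
#'
#' The smallest count of parallel analyses that constitutes strictly more
#' than 50% of them: `floor(K / 2) + 1`. With 24 parallel g estimates an
#' ROI must be significant in at least 13 of them to be accepted.
#'
#' @param K Number of parallel analyses (positive integer).
#' @return Integer threshold.
#' @examples
#' consensus_threshold(24)
#' @export
consensus_threshold <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be a positive integer", call. = FALSE)
  K %/% 2L + 1L
}

#' Apply the majority-vote consensus rule to a significance matrix
#'
#' An ROI is accepted as a reliable correlate of g only if it is
#' significant in strictly more than half of the parallel g-set analyses;
#' ROIs below that bar are rejected as possible false positives. The
#' report also gives per-g-set coverage (how many ROIs each g estimate
#' detected), flags near misses (count exactly one below threshold, where
#' the rule's stringency is most debatable), and summarizes the sign
#' consistency of the significant effects per ROI.
#'
#' @param assoc A `roi_association` from [build_significance_matrix()], or
#'   a bare logical ROI x g-set matrix.
#' @return An object of class `consensus_report`: list with
#'   `roi` (tibble: `roi`, `n_significant`, `threshold`, `accepted`,
#'   `near_miss`, `sign_consistent`, `direction`), `gset` (tibble:
#'   `combo_id`, `n_rois_significant`), `K` and `threshold`.
#' @export
apply_consensus <- function(assoc) {
  if (inherits(assoc, "roi_association")) {
    sig <- assoc$significance
    results <- assoc$results
  } else {
    sig <- as.matrix(assoc)
    if (!is.logical(sig)) storage.mode(sig) <- "logical"
    results <- NULL
  }
  if (!length(sig)) stop("significance matrix is empty", call. = FALSE)
  K <- ncol(sig)
  thr <- consensus_threshold(K)
  counts <- rowSums(sig)

  direction <- rep(NA_character_, nrow(sig))
  sign_consistent <- rep(NA, nrow(sig))
  if (!is.null(results)) {
    for (i in seq_len(nrow(sig))) {
      rr <- results[results$roi == rownames(sig)[i] & results$significant, ]
      if (nrow(rr)) {
        s <- sign(rr$r)
        sign_consistent[i] <- length(unique(s)) == 1L
        direction[i] <- if (all(s > 0)) "positive"
                        else if (all(s < 0)) "negative" else "mixed"
      }
    }
  }

  roi_tab <- tibble::tibble(
    roi = if (!is.null(rownames(sig))) rownames(sig)
          else paste0("roi_", seq_len(nrow(sig))),
    n_significant = as.integer(counts),
    threshold = thr,
    accepted = counts >= thr,
    near_miss = counts == thr - 1L,
    sign_consistent = sign_consistent,
    direction = direction
  )
  gset_tab <- tibble::tibble(
    combo_id = if (!is.null(colnames(sig))) colnames(sig)
               else paste0("gset_", seq_len(K)),
    n_rois_significant = as.integer(colSums(sig))
  )
  structure(
    list(roi = roi_tab, gset = gset_tab, K = K, threshold = thr,
         measure = if (inherits(assoc, "roi_association")) assoc$measure
                   else NULL),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  acc <- x$roi[x$roi$accepted, ]
  cat("<consensus_report>", if (!is.null(x$measure)) x$measure else "",
      nrow(x$roi), "ROIs x", x$K, "g score sets; threshold",
      x$threshold, "\n")
  if (nrow(acc)) {
    cat("accepted ROIs:\n")
    for (i in seq_len(nrow(acc))) {
      cat(sprintf("  %-40s %2d/%d%s\n", acc$roi[i], acc$n_significant[i],
                  x$K,
                  if (!is.na(acc$direction[i]))
                    paste0(" (", acc$direction[i], ")") else ""))
    }
  } else {
    cat("no ROI accepted\n")
  }
  nm <- sum(x$roi$near_miss)
  if (nm) cat(nm, "near-miss ROI(s) one short of threshold\n")
  invisible(x)
}

#' Accepted ROI labels from a consensus report
#'
#' @param report A [apply_consensus()] result.
#' @return Character vector of accepted ROI labels.
#' @export
accepted_rois <- function(report) {
  stopifnot(inherits(report, "consensus_report"))
  report$roi$roi[report$roi$accepted]
}
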