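# Partial-F p-value for adding/keeping single terms, robust to perfect fits
# (zero residual sums of squares give p = 0, not NaN).
partial_f_p <- function(rss0, rss1, df1) {
  if (df1 < 1L) return(NA_real_)
  num <- max(rss0 - rss1, 0)
  if (rss1 <= num * 1e-12) return(if (num > 0) 0 else 1)
  stats::pf(num / (rss1 / df1), 1, df1, lower.tail = FALSE)
}

ols_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Stepwise linear model of g on ROI morphometry
#'
#' Forward-backward stepwise selection by partial-F p-value (enter when
#' p < `p_enter`, remove when p > `p_remove`), followed by an ordinary
#' least-squares fit of the selected predictors:
#' `Y = b0 + b1 X1 + b2 X2 + ... + e`, where Y is the g score and the X's
#' are ROI morphometry values. When no candidate enters, the intercept-only
#' model is returned and flagged.
#'
#' @param X Data frame or matrix of candidate predictors (one column per
#'   accepted ROI measure).
#' @param y Numeric response (a g score vector).
#' @param p_enter,p_remove Partial-F thresholds for entering (0.05) and
#'   removing (0.10) a predictor.
#' @param combo_id Optional label of the g score set being modelled.
#' @return An object of class `g_estimation_model`: list with `intercept`,
#'   `coefficients` (named, selected predictors only), `selected`,
#'   `r_squared`, `adj_r_squared`, `residual_sd`, `n`, `empty` (no
#'   predictor entered), `combo_id` and the selection `path`.
#' @examples
#' x <- rnorm(50)
#' m <- stepwise_fit(data.frame(x = x), 3 + 2 * x)
#' coef(m)
#' @export
stepwise_fit <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                         combo_id = NULL) {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("`X` and `y` sizes differ", call. = FALSE)
  cand <- names(X)
  if (n <= length(cand) + 2L) {
    stop("need n > number of candidate predictors + 2", call. = FALSE)
  }
  Xm <- as.matrix(X)
  one <- matrix(1, n, 1)

  selected <- character(0)
  path <- list()
  repeat {
    changed <- FALSE
    # forward: best candidate by partial F
    avail <- setdiff(cand, selected)
    if (length(avail)) {
      base_X <- cbind(one, Xm[, selected, drop = FALSE])
      rss0 <- ols_rss(base_X, y)
      df1 <- n - ncol(base_X) - 1L
      ps <- vapply(avail, function(j) {
        partial_f_p(rss0, ols_rss(cbind(base_X, Xm[, j]), y), df1)
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        j <- avail[which.min(ps)]
        selected <- c(selected, j)
        path[[length(path) + 1L]] <- list(step = "add", term = j,
                                          p = min(ps, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward: drop worst retained term while its removal p exceeds p_remove
    repeat {
      if (length(selected) == 0L) break
      full_X <- cbind(one, Xm[, selected, drop = FALSE])
      rss1 <- ols_rss(full_X, y)
      df1 <- n - ncol(full_X)
      ps <- vapply(selected, function(j) {
        keep <- setdiff(selected, j)
        rss0 <- ols_rss(cbind(one, Xm[, keep, drop = FALSE]), y)
        partial_f_p(rss0, rss1, df1)
      }, numeric(1))
      if (max(ps) > p_remove) {
        j <- selected[which.max(ps)]
        selected <- setdiff(selected, j)
        path[[length(path) + 1L]] <- list(step = "drop", term = j,
                                          p = max(ps))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  df_resid <- n - length(selected) - 1L
  if (length(selected)) {
    Xfull <- cbind(`(Intercept)` = one[, 1], Xm[, selected, drop = FALSE])
    qx <- qr(Xfull)
    coefs <- qr.coef(qx, y)
    rss <- sum(qr.resid(qx, y)^2)
    se <- sqrt(diag(chol2inv(qr.R(qx))) * rss / max(df_resid, 1L))
  } else {
    coefs <- c(`(Intercept)` = mean(y))
    rss <- sum((y - mean(y))^2)
    se <- sqrt(rss / max(df_resid, 1L) / n)
  }
  tstat <- coefs / se
  pvals <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_resid else NA_real_

  structure(
    list(
      intercept = unname(coefs[1]),
      coefficients = if (length(selected)) coefs[-1][selected]
                     else stats::setNames(numeric(0), character(0)),
      selected = selected,
      std_errors = stats::setNames(as.numeric(se), names(coefs)),
      t_values = stats::setNames(as.numeric(tstat), names(coefs)),
      p_values = stats::setNames(as.numeric(pvals), names(coefs)),
      r_squared = r2, adj_r_squared = adj_r2,
      residual_sd = sqrt(rss / max(df_resid, 1L)),
      n = n, empty = length(selected) == 0L,
      p_enter = p_enter, p_remove = p_remove,
      combo_id = combo_id, path = path
    ),
    class = "g_estimation_model"
  )
}

#' @export
coef.g_estimation_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.g_estimation_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss)) {
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- rep(object$intercept, nrow(newdata))
  for (j in object$selected) {
    out <- out + object$coefficients[[j]] * newdata[[j]]
  }
  out
}

#' @export
print.g_estimation_model <- function(x, ...) {
  cat("<g_estimation_model>",
      if (!is.null(x$combo_id)) x$combo_id else "", "\n")
  if (x$empty) {
    cat("  intercept-only (no predictor passed p_enter)\n")
  } else {
    cat("  g =", format(round(x$intercept, 3)),
        paste(sprintf("%+0.3f*%s", x$coefficients, x$selected),
              collapse = " "), "\n")
  }
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, residual SD = %.3f, n = %d\n",
              x$r_squared, x$adj_r_squared, x$residual_sd, x$n))
  invisible(x)
}

#' K-fold cross-validation of the stepwise g-estimation model
#'
#' Shuffles subjects with the given seed, splits them into K folds of
#' near-equal size (differing by at most one), and re-runs the entire
#' stepwise selection inside each training fold before predicting the held
#' out fold, so no information leaks from test to training data. Held-out
#' predictions are pooled into a mean squared error of prediction; an
#' outlier-excluded MSE drops predictions whose absolute residual exceeds
#' 3 robust (MAD-scaled) SDs of the pooled residuals.
#'
#' @inheritParams stepwise_fit
#' @param K Number of folds (>= 2).
#' @param seed Integer seed for the fold shuffle.
#' @param refit_within_folds Re-run stepwise selection inside each training
#'   fold (default, leak-free). `FALSE` reproduces the leaky variant that
#'   selects predictors once on the full data and only refits coefficients
#'   per fold; provided for comparison only.
#' @return An object of class `cv_result`: list with `K`, `folds` (integer
#'   assignment per subject), `predictions` (tibble: `index`, `fold`,
#'   `observed`, `predicted`, `residual`, `outlier`), `mse_pooled`,
#'   `mse_excl_outliers`, `outlier_rule`, `n_outliers`, `fold_models`,
#'   `seed`.
#' @export
kfold_validate <- function(X, y, K = 4, seed = 1L, p_enter = 0.05,
                           p_remove = 0.10, refit_within_folds = TRUE,
                           combo_id = NULL) {
  X <- as.data.frame(X)
  n <- length(y)
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  if (n < K) stop("need at least K subjects", call. = FALSE)

  folds <- integer(n)
  with_seed(seed, {
    folds[sample.int(n)] <- rep_len(seq_len(K), n)
  })

  full_selection <- if (!refit_within_folds) {
    stepwise_fit(X, y, p_enter, p_remove)$selected
  } else NULL

  pred <- rep(NA_real_, n)
  fold_models <- vector("list", K)
  for (k in seq_len(K)) {
    test <- folds == k
    ytr <- y[!test]
    if (stats::sd(ytr) == 0) {
      stop("training fold ", k, " has zero variance in the response",
           call. = FALSE)
    }
    if (refit_within_folds) {
      m <- stepwise_fit(X[!test, , drop = FALSE], ytr, p_enter, p_remove)
    } else {
      sel <- full_selection
      if (length(sel)) {
        fit <- stats::lm.fit(cbind(1, as.matrix(X[!test, sel, drop = FALSE])),
                             ytr)
        m <- list(intercept = unname(fit$coefficients[1]),
                  coefficients = stats::setNames(fit$coefficients[-1], sel),
                  selected = sel, empty = FALSE)
        class(m) <- "g_estimation_model"
      } else {
        m <- stepwise_fit(X[!test, , drop = FALSE], ytr, p_enter = -1,
                          p_remove = 0)   # forces intercept-only
      }
    }
    fold_models[[k]] <- m
    pred[test] <- predict(m, X[test, , drop = FALSE])
  }

  resid <- y - pred
  rsd <- stats::mad(resid)
  # residuals at floating-point noise level are never outliers
  floor_tol <- 1e-8 * max(stats::sd(y), 1e-12)
  outlier <- abs(resid) > pmax(3 * rsd, floor_tol)
  mse_pooled <- mean(resid^2)
  mse_excl <- if (all(outlier)) NA_real_ else mean(resid[!outlier]^2)

  structure(
    list(
      K = K, folds = folds,
      predictions = tibble::tibble(
        index = seq_len(n), fold = folds, observed = y, predicted = pred,
        residual = resid, outlier = outlier
      ),
      mse_pooled = mse_pooled, mse_excl_outliers = mse_excl,
      outlier_rule = "|residual| > 3 * mad(residuals)",
      n_outliers = sum(outlier),
      fold_models = fold_models, seed = seed,
      refit_within_folds = refit_within_folds, combo_id = combo_id
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV, n = %d: MSE %.3f (%.3f excluding %d outlier%s)\n",
    x$K, nrow(x$predictions), x$mse_pooled, x$mse_excl_outliers,
    x$n_outliers, if (x$n_outliers == 1) "" else "s"))
  invisible(x)
}

#' Fit and cross-validate one g-estimation model per g score set
#'
#' For every parallel g estimate, builds the stepwise linear model of g on
#' the accepted ROI predictors and cross-validates it with K folds, then
#' summarizes adjusted R-squared across models, per-predictor selection
#' frequency, and identifies the best and worst models.
#'
#' @param predictors Tibble/data frame of candidate predictors over
#'   subjects (e.g. from [morph_predictors()]); a `subject_id` column, if
#'   present, is checked against the g score sets and dropped.
#' @param gsets List of `g_score_set` objects.
#' @param K Folds for cross-validation (default 4).
#' @param seed Integer seed (fold shuffles are derived from it).
#' @inheritParams stepwise_fit
#' @return An object of class `g_model_suite`: list with `summary` (tibble:
#'   `combo_id`, `n_selected`, `r_squared`, `adj_r_squared`, `mse_pooled`,
#'   `mse_excl_outliers`, `n_outliers`), `models`, `cv`, `selection_freq`
#'   (tibble: `predictor`, `times_selected`, `freq`), `median_adj_r2`,
#'   `range_adj_r2`, `best_combo`, `worst_combo`.
#' @export
run_all_models <- function(predictors, gsets, K = 4, seed = 1L,
                           p_enter = 0.05, p_remove = 0.10) {
  predictors <- tibble::as_tibble(predictors)
  if ("subject_id" %in% names(predictors)) {
    for (gs in gsets) {
      if (inherits(gs, "g_score_set") &&
          !identical(gs$subject_id, predictors$subject_id)) {
        stop("predictor table subjects do not align with g score sets",
             call. = FALSE)
      }
    }
    predictors$subject_id <- NULL
  }

  models <- vector("list", length(gsets))
  cvs <- vector("list", length(gsets))
  rows <- vector("list", length(gsets))
  for (i in seq_along(gsets)) {
    gs <- gsets[[i]]
    cid <- if (inherits(gs, "g_score_set")) gs$combo_id else paste0("gset_", i)
    y <- if (inherits(gs, "g_score_set")) gs$scores else as.numeric(gs)
    m <- stepwise_fit(predictors, y, p_enter, p_remove, combo_id = cid)
    cv <- kfold_validate(predictors, y, K = K, seed = seed + i,
                         p_enter = p_enter, p_remove = p_remove,
                         combo_id = cid)
    models[[i]] <- m
    cvs[[i]] <- cv
    rows[[i]] <- tibble::tibble(
      combo_id = cid, n_selected = length(m$selected),
      r_squared = m$r_squared, adj_r_squared = m$adj_r_squared,
      mse_pooled = cv$mse_pooled, mse_excl_outliers = cv$mse_excl_outliers,
      n_outliers = cv$n_outliers
    )
  }
  summary_tab <- dplyr::bind_rows(rows)

  sel_counts <- table(factor(
    unlist(lapply(models, function(m) m$selected)),
    levels = names(predictors)
  ))
  selection_freq <- tibble::tibble(
    predictor = names(sel_counts),
    times_selected = as.integer(sel_counts),
    freq = as.numeric(sel_counts) / length(gsets)
  )

  ord <- order(summary_tab$adj_r_squared)
  structure(
    list(
      summary = summary_tab, models = models, cv = cvs,
      selection_freq = selection_freq,
      median_adj_r2 = stats::median(summary_tab$adj_r_squared),
      range_adj_r2 = range(summary_tab$adj_r_squared),
      best_combo = summary_tab$combo_id[ord[length(ord)]],
      worst_combo = summary_tab$combo_id[ord[1]],
      K = K, seed = seed
    ),
    class = "g_model_suite"
  )
}

#' @export
print.g_model_suite <- function(x, ...) {
  cat(sprintf(
    "<g_model_suite> %d models; adj R2 median %.3f (range %.3f-%.3f); %d-fold CV\n",
    nrow(x$summary), x$median_adj_r2, x$range_adj_r2[1], x$range_adj_r2[2],
    x$K))
  top <- x$selection_freq[order(-x$selection_freq$freq), ]
  top <- top[top$times_selected > 0, ]
  if (nrow(top)) {
    cat("most frequently selected:",
        paste(sprintf("%s (%d/%d)", utils::head(top$predictor, 3),
                      utils::head(top$times_selected, 3), nrow(x$summary)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble candidate predictors from accepted ROIs
#'
#' Joins the accepted cortical thickness and gyrification ROI columns into
#' one predictor table, prefixing column names with the measure
#' (`ct_`, `lgi_`) so the same region can contribute both measures.
#'
#' @param ct,lgi Morphometry tibbles (`subject_id`, covariates, ROI
#'   columns).
#' @param ct_rois,lgi_rois Character vectors of accepted ROI labels per
#'   measure (e.g. from [accepted_rois()]).
#' @return Tibble: `subject_id` plus one column per accepted ROI-measure.
#' @export
morph_predictors <- function(ct, lgi, ct_rois, lgi_rois) {
  ct <- tibble::as_tibble(ct)
  lgi <- tibble::as_tibble(lgi)
  if (!identical(ct$subject_id, lgi$subject_id)) {
    stop("CT and LGI tables have mismatched subjects", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = ct$subject_id)
  for (roi in ct_rois) out[[paste0("ct_", roi)]] <- ct[[roi]]
  for (roi in lgi_rois) out[[paste0("lgi_", roi)]] <- lgi[[roi]]
  out
}
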