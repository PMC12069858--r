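#' Read a subject score table
#'
#' @param path CSV/TSV file with a `subject_id` column, one column per
#'   test, `<test>_time` columns for timed tests, and `gender` /
#'   `handedness` covariates.
#' @return A tibble.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tibble::as_tibble(utils::read.delim(path, sep = sep, check.names = FALSE))
}

#' Read a wide morphometry table
#'
#' Reads an `aparcstats2table`-style wide table: first column the subject
#' id, remaining columns one per ROI (plus optional `gender` /
#' `handedness` covariate columns).
#'
#' @param path CSV/TSV file.
#' @param measure Measure label, e.g. `"CT"` or `"LGI"`.
#' @return A tibble with `attr(, "measure")` set.
#' @export
read_morphometry <- function(path, measure) {
  if (!file.exists(path)) {
    stop("morphometry table not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tibble::as_tibble(utils::read.delim(path, sep = sep,
                                             check.names = FALSE))
  names(tab)[1] <- "subject_id"
  if (anyNA(tab)) stop("morphometry table has missing cells", call. = FALSE)
  if (anyDuplicated(setdiff(names(tab), "subject_id"))) {
    stop("duplicated ROI column names", call. = FALSE)
  }
  attr(tab, "measure") <- measure
  tab
}

#' Configure a pipeline run
#'
#' Exactly one of `cohort` (a [cohort_config()] for a synthetic run) or
#' `paths` (named list with `scores`, `ct`, `lgi` CSV/TSV files) must be
#' given.
#'
#' @param cohort Optional [cohort_config()].
#' @param paths Optional named list of input file paths.
#' @param battery [battery()] describing the tests (default
#'   [default_battery()]).
#' @param alpha Significance level for the permutation tests.
#' @param n_perm Permutations per g-set/measure analysis.
#' @param K Cross-validation folds.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param output_dir Directory for run artifacts; `NULL` skips writing.
#' @param split_networks Correct the DMN and TPN ROI families separately
#'   (default `TRUE`; requires ROI labels to match [roi_labels()],
#'   otherwise all ROIs form a single family).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, paths = NULL,
                            battery = default_battery(), alpha = 0.05,
                            n_perm = 5000, K = 4, seed = 1L,
                            output_dir = NULL, split_networks = TRUE) {
  if (is.null(cohort) == is.null(paths)) {
    stop("provide exactly one of `cohort` (synthetic) or `paths` (files)",
         call. = FALSE)
  }
  if (!is.null(paths)) {
    need <- c("scores", "ct", "lgi")
    if (!all(need %in% names(paths))) {
      stop("`paths` must name files for: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    missing_files <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(missing_files)) {
      stop("input file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(cohort = cohort, paths = paths, battery = battery, alpha = alpha,
         n_perm = as.integer(n_perm), K = as.integer(K),
         seed = as.integer(seed), output_dir = output_dir,
         split_networks = split_networks),
    class = "pipeline_config"
  )
}

#' Run the full consensus g pipeline
#'
#' Executes the stages in sequence: score conditioning, parallel g
#' estimation over all test combinations with the positive-manifold
#' summary, permutation-FWE association of every ROI with every g score
#' set (cortical thickness first, then gyrification), the majority-vote
#' consensus over ROIs, and stepwise g-estimation models from the accepted
#' ROIs with K-fold cross-validation. When `output_dir` is set, every
#' stage's tables are written as CSV together with a JSON manifest
#' (package version, seeds, parameters, input digests, collected warnings)
#' that makes the run reproducible.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `conditioned`,
#'   `gsets`, `manifold`, `assoc` (list `ct`, `lgi`), `consensus` (list
#'   `ct`, `lgi`), `predictors`, `models` (a `g_model_suite`, `NULL` when
#'   no ROI was accepted), `truth` (synthetic runs only), `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = cohort_config(seed = 11), n_perm = 200)
#' res <- run_pipeline(cfg)
#' res$consensus$ct
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage `", stage, "` failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  bat <- config$battery
  if (!is.null(config$cohort)) {
    cohort <- collect(generate_cohort(config$cohort), "simulate")
    scores <- cohort$scores
    ct <- cohort$ct
    lgi <- cohort$lgi
    truth <- cohort$truth
    input_digests <- list(synthetic_seed = config$cohort$seed)
  } else {
    scores <- collect(read_scores(config$paths$scores), "load")
    ct <- collect(read_morphometry(config$paths$ct, "CT"), "load")
    lgi <- collect(read_morphometry(config$paths$lgi, "LGI"), "load")
    truth <- NULL
    input_digests <- as.list(tools::md5sum(unlist(config$paths)))
  }

  conditioned <- collect(condition_battery(scores, bat, config$alpha),
                         "condition")
  gsets <- collect(estimate_all_g(conditioned), "gfactor")
  manifold <- collect(manifold_summary(gsets), "gfactor")

  fam <- NULL
  if (config$split_networks) {
    labs <- roi_labels()
    map <- stats::setNames(labs$network, labs$roi)
    roi_cols <- setdiff(names(ct), c("subject_id", "gender", "handedness"))
    if (all(roi_cols %in% names(map))) fam <- map
  }

  assoc_ct <- collect(
    build_significance_matrix(ct, gsets, n_perm = config$n_perm,
                              alpha = config$alpha, seed = config$seed,
                              families = fam),
    "associate-ct")
  assoc_lgi <- collect(
    build_significance_matrix(lgi, gsets, n_perm = config$n_perm,
                              alpha = config$alpha,
                              seed = config$seed + 1000L, families = fam),
    "associate-lgi")

  cons_ct <- collect(apply_consensus(assoc_ct), "consensus")
  cons_lgi <- collect(apply_consensus(assoc_lgi), "consensus")

  preds <- collect(
    morph_predictors(ct, lgi, accepted_rois(cons_ct),
                     accepted_rois(cons_lgi)),
    "predict")
  models <- NULL
  if (ncol(preds) > 1L &&
      nrow(preds) > (ncol(preds) - 1L) + 2L) {
    models <- collect(
      run_all_models(preds, gsets, K = config$K, seed = config$seed + 2000L),
      "predict")
  }

  manifest <- list(
    package = "gmanifold",
    version = as.character(utils::packageVersion("gmanifold")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed, alpha = config$alpha, n_perm = config$n_perm,
    K = config$K, split_networks = config$split_networks,
    n_subjects = nrow(conditioned$scores),
    n_combinations = length(gsets),
    consensus_threshold = consensus_threshold(length(gsets)),
    input_digests = input_digests,
    warnings = warnings_log
  )

  result <- structure(
    list(conditioned = conditioned, gsets = gsets, manifold = manifold,
         assoc = list(ct = assoc_ct, lgi = assoc_lgi),
         consensus = list(ct = cons_ct, lgi = cons_lgi),
         predictors = preds, models = models, truth = truth,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_result(result, config$output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_subjects, "subjects,",
      x$manifest$n_combinations, "g score sets\n")
  print(x$manifold)
  cat("accepted CT ROIs: ",
      paste(accepted_rois(x$consensus$ct), collapse = ", "), "\n",
      "accepted LGI ROIs: ",
      paste(accepted_rois(x$consensus$lgi), collapse = ", "), "\n", sep = "")
  if (!is.null(x$models)) print(x$models)
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)

  write_conditioned(result$conditioned, dir)
  gm <- gscore_matrix(result$gsets)
  w(cbind(subject_id = rownames(gm), as.data.frame(gm)), "g_scores.csv")
  cm <- result$manifold$cor_matrix
  w(cbind(combo_id = rownames(cm), as.data.frame(cm)), "manifold_cor.csv")
  for (m in c("ct", "lgi")) {
    w(result$assoc[[m]]$results, paste0("association_", m, ".csv"))
    sg <- result$assoc[[m]]$significance
    w(cbind(roi = rownames(sg), as.data.frame(sg)),
      paste0("significance_", m, ".csv"))
    w(result$consensus[[m]]$roi, paste0("consensus_", m, ".csv"))
  }
  if (!is.null(result$models)) {
    w(result$models$summary, "model_summary.csv")
    w(result$models$selection_freq, "selection_frequency.csv")
    best <- which(vapply(result$models$cv, function(cv) cv$combo_id,
                         character(1)) == result$models$best_combo)[1]
    worst <- which(vapply(result$models$cv, function(cv) cv$combo_id,
                          character(1)) == result$models$worst_combo)[1]
    w(result$models$cv[[best]]$predictions, "cv_predictions_best.csv")
    w(result$models$cv[[worst]]$predictions, "cv_predictions_worst.csv")
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
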