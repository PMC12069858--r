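#' Time-weight a speeded test score
#'
#' Converts a raw score and a completion time into an efficiency score,
#' `raw / time` (correct output per unit time), the standard throughput
#' metric for speeded tests.
#'
#' @param raw Numeric vector of raw scores.
#' @param time Numeric vector of completion times, strictly positive, same
#'   length as `raw`.
#' @return Numeric vector `raw / time`.
#' @examples
#' time_weight(c(10, 6), c(2, 3))
#' @export
time_weight <- function(raw, time) {
  if (length(raw) != length(time)) {
    stop("`raw` and `time` must have the same length", call. = FALSE)
  }
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    stop("nonpositive or missing completion time for subject(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw / time
}

#' Shapiro-Wilk normality screen
#'
#' Tests a score vector for normality and reports whether it passes at the
#' given level. Sample sizes must lie in the validity range of the
#' Shapiro-Wilk test (3 to 5000).
#'
#' @param x Numeric vector, no missing values, non-constant.
#' @param alpha Significance level; the screen passes when `p >= alpha`.
#' @return A list with `is_normal` (logical) and `p` (the Shapiro-Wilk
#'   p-value).
#' @export
normality_screen <- function(x, alpha = 0.05) {
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop("normality screen supports 3 <= n <= 5000, got n = ", n,
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("normality screen undefined for a zero-variance vector",
         call. = FALSE)
  }
  p <- stats::shapiro.test(x)$p.value
  list(is_normal = p >= alpha, p = p)
}

# z-standardize, guarding the zero-variance case with an informative error.
zstd <- function(x, what = "column") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize zero-variance ", what, call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Condition a battery of raw test scores
#'
#' Applies the full score-conditioning sequence to every test in the
#' battery: timed tests are first converted to efficiency scores
#' (score / completion time), each score vector is screened for normality
#' with the Shapiro-Wilk test, non-normal scores are log-transformed
#' (`log(x + c)` with offset `c = 1 - min(x)` when the support includes
#' nonpositive values, else `c = 0`), reverse-scored tests are negated so
#' that a higher conditioned score always means better performance, and
#' every column is z-standardized. A provenance record documents exactly
#' what was done to each test.
#'
#' @param scores Tibble/data frame with a `subject_id` column, one raw
#'   score column per battery test, a `<test>_time` column for every timed
#'   test, and (optionally) covariate columns which are carried through.
#' @param battery A [battery()] object.
#' @param alpha Normality-screen level (default 0.05).
#' @return An object of class `conditioned_scores`: a list with
#'   `scores` (tibble: `subject_id`, covariates if present, one
#'   standardized column per test) and `provenance` (tibble: `test`,
#'   `time_weighted`, `shapiro_p`, `log_transformed`, `log_offset`,
#'   `direction_flipped`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 60, seed = 2))
#' cs <- condition_battery(coh$scores, default_battery())
#' cs$provenance
#' @export
condition_battery <- function(scores, battery, alpha = 0.05) {
  stopifnot(inherits(battery, "battery"))
  scores <- tibble::as_tibble(scores)
  if (!"subject_id" %in% names(scores)) {
    stop("score table must contain a `subject_id` column", call. = FALSE)
  }
  if (anyNA(scores$subject_id) || anyDuplicated(scores$subject_id)) {
    stop("subject ids must be present and unique", call. = FALSE)
  }
  tests <- battery_tests(battery)
  missing_cols <- setdiff(tests, names(scores))
  if (length(missing_cols)) {
    stop("score table is missing test column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(subject_id = scores$subject_id)
  for (cov in intersect(c("gender", "handedness"), names(scores))) {
    out[[cov]] <- scores[[cov]]
  }

  prov <- purrr::map_dfr(tests, function(tst) {
    x <- scores[[tst]]
    if (anyNA(x)) stop("missing values in test `", tst, "`", call. = FALSE)
    timed <- tst %in% battery$timed_tests
    if (timed) {
      tcol <- paste0(tst, "_time")
      if (!tcol %in% names(scores)) {
        stop("timed test `", tst, "` has no `", tcol, "` column",
             call. = FALSE)
      }
      x <- time_weight(x, scores[[tcol]])
    }
    scr <- normality_screen(x, alpha)
    offset <- 0
    logged <- !scr$is_normal
    if (logged) {
      if (min(x) <= 0) offset <- 1 - min(x)
      x <- log(x + offset)
    }
    flip <- !battery$direction[[tst]]
    if (flip) x <- -x
    out[[tst]] <<- zstd(x, paste0("test `", tst, "`"))
    tibble::tibble(
      test = tst, time_weighted = timed, shapiro_p = scr$p,
      log_transformed = logged, log_offset = offset,
      direction_flipped = flip
    )
  })

  structure(list(scores = out, provenance = prov, alpha = alpha,
                 battery = battery),
            class = "conditioned_scores")
}

#' @export
print.conditioned_scores <- function(x, ...) {
  cat("<conditioned_scores>", nrow(x$scores), "subjects,",
      nrow(x$provenance), "tests (",
      sum(x$provenance$time_weighted), "time-weighted,",
      sum(x$provenance$log_transformed), "log-transformed )\n")
  invisible(x)
}

#' Write conditioned scores and their provenance
#'
#' @param conditioned A [condition_battery()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_conditioned <- function(conditioned, dir) {
  stopifnot(inherits(conditioned, "conditioned_scores"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scores = file.path(dir, "conditioned_scores.csv"),
             provenance = file.path(dir, "conditioning_provenance.json"))
  utils::write.csv(conditioned$scores, paths[["scores"]], row.names = FALSE)
  jsonlite::write_json(list(alpha = conditioned$alpha,
                            provenance = conditioned$provenance),
                       paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
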