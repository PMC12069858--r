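#' ROI labels for the default and task-positive networks
#'
#' The 25 regions of interest the pipeline analyses by default: 17 nodes of
#' the default mode network (DMN) and 8 nodes of the task-positive network
#' (TPN), named after their Destrieux-atlas parcels. Only the labels are
#' used here; no surface geometry is involved.
#'
#' @return A tibble with columns `roi` (character label) and `network`
#'   (`"DMN"` or `"TPN"`).
#' @export
roi_labels <- function() {
  dmn <- c(
    "dorsal_posterior_cingulate", "ventral_posterior_cingulate", "precuneus",
    "subparietal_sulcus", "angular_gyrus", "straight_gyrus",
    "subcallosal_gyrus", "suborbital_sulcus", "superior_frontal_gyrus",
    "inferior_temporal_gyrus", "middle_temporal_gyrus", "planum_polare",
    "temporal_sulci", "temporal_pole", "collateral_sulcus",
    "lingual_medial_occipitotemporal_sulcus", "parahippocampal_gyrus"
  )
  tpn <- c(
    "supramarginal_gyrus", "superior_frontal_sulcus", "inferior_frontal_sulcus",
    "triangular_inferior_frontal_gyrus", "middle_anterior_cingulate",
    "marginal_cingulate_sulcus", "long_insular_gyrus", "short_insular_gyri"
  )
  tibble::tibble(
    roi = c(dmn, tpn),
    network = rep(c("DMN", "TPN"), c(length(dmn), length(tpn)))
  )
}

#' Default true g effects on cortical thickness
#'
#' Standardized effects of latent g on ROI-mean cortical thickness for the
#' three DMN regions carrying true (negative: thinner cortex, higher g)
#' effects in the default simulation scenario. Magnitudes are chosen so the
#' population covariate-adjusted correlation falls in the -0.25 to -0.52
#' band typical of ROI-level thickness associations in small adult cohorts.
#'
#' @return Named numeric vector of standardized slopes.
#' @export
default_ct_effects <- function() {
  c(
    inferior_temporal_gyrus     = -0.60,
    ventral_posterior_cingulate = -0.50,
    parahippocampal_gyrus       = -0.40
  )
}

#' Default true g effects on local gyrification
#'
#' Positive effects (more folding, higher g) on the five DMN regions that
#' carry true local gyrification index (LGI) effects in the default
#' scenario; magnitudes give population correlations in the 0.22-0.41 band.
#'
#' @return Named numeric vector of standardized slopes.
#' @export
default_lgi_effects <- function() {
  c(
    ventral_posterior_cingulate            = 0.45,
    dorsal_posterior_cingulate             = 0.42,
    middle_temporal_gyrus                  = 0.38,
    collateral_sulcus                      = 0.33,
    lingual_medial_occipitotemporal_sulcus = 0.28
  )
}

#' Configure a synthetic cohort
#'
#' Encodes the generative model the rest of the pipeline assumes: a
#' standard-normal latent g, a battery of tests loading on it with shared
#' within-domain nuisance variation, gender and handedness covariates
#' independent of g, and ROI morphometry values that are linear in g and
#' the covariates with unit-variance Gaussian residuals.
#'
#' For test j in domain d the latent test variable is
#' `v_ij = lambda_j * g_i + delta * u_id + sigma * e_ij` with `u`, `e`
#' independent standard normal, `delta = domain_noise_sd` and
#' `sigma = test_noise_sd`. Tests listed in `skewed_tests` are observed on
#' the exponentiated scale `exp(v)`; timed tests are observed as raw score
#' = (observed efficiency) x (an independent lognormal completion time), so
#' that score-per-unit-time recovers the latent variable. ROI value for
#' region r is `beta_r * g_i + gamma1_r * gender_i + gamma2_r * hand_i +
#' eps_ir` with `eps` standard normal.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param battery A [battery()] object; defaults to [default_battery()].
#' @param loading_range Length-2 numeric in (0, 1]; per-test loadings
#'   `lambda_j` are drawn uniformly from this interval (a degenerate
#'   interval fixes them).
#' @param domain_noise_sd,test_noise_sd Nonnegative SDs of the shared
#'   within-domain nuisance factor and the test-specific residual.
#' @param ct_effects,lgi_effects Named numeric vectors mapping ROI labels to
#'   the standardized effect of g on that ROI's cortical thickness / LGI.
#'   ROIs not named carry no effect.
#' @param covariate_effects Either `NULL` (every ROI gets the default
#'   `c(gender = 0.1, handedness = 0.05)`) or a named list mapping ROI
#'   labels to length-2 numeric `(gamma_gender, gamma_handedness)`.
#' @param skewed_tests Character vector of tests observed on the
#'   exponentiated scale (default: the math and logic tests).
#' @param rois Tibble of ROI labels as from [roi_labels()].
#' @param handedness_probs Probabilities over handedness ranks `1:length()`;
#'   default puts 80% of subjects at the maximum (fully right-handed) rank.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 44,
                          battery = default_battery(),
                          loading_range = c(0.65, 0.85),
                          domain_noise_sd = 0.25,
                          test_noise_sd = 0.5,
                          ct_effects = default_ct_effects(),
                          lgi_effects = default_lgi_effects(),
                          covariate_effects = NULL,
                          skewed_tests = c("math_puzzles", "logical_reasoning"),
                          rois = roi_labels(),
                          handedness_probs = c(0.05, 0.05, 0.05, 0.05, 0.80),
                          seed = 1L) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects), battery = battery,
      loading_range = as.numeric(loading_range),
      domain_noise_sd = as.numeric(domain_noise_sd),
      test_noise_sd = as.numeric(test_noise_sd),
      ct_effects = ct_effects, lgi_effects = lgi_effects,
      covariate_effects = covariate_effects,
      skewed_tests = as.character(skewed_tests), rois = rois,
      handedness_probs = as.numeric(handedness_probs),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid cohort config: `", field, "` ", msg, call. = FALSE)
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 4L) {
    fail("n_subjects", "must be at least 4 (minimum for a 4-variable factor fit)")
  }
  if (!inherits(cfg$battery, "battery")) fail("battery", "must be a battery object")
  lr <- cfg$loading_range
  if (length(lr) != 2L || any(!is.finite(lr)) || lr[1] > lr[2] ||
      lr[1] <= 0 || lr[2] > 1) {
    fail("loading_range", "must be an ordered pair within (0, 1]")
  }
  if (cfg$domain_noise_sd < 0) fail("domain_noise_sd", "must be nonnegative")
  if (cfg$test_noise_sd < 0) fail("test_noise_sd", "must be nonnegative")
  roi_names <- cfg$rois$roi
  if (anyDuplicated(roi_names)) fail("rois", "contains duplicated ROI labels")
  for (fld in c("ct_effects", "lgi_effects")) {
    eff <- cfg[[fld]]
    if (length(eff)) {
      if (is.null(names(eff)) || !all(names(eff) %in% roi_names)) {
        fail(fld, "names ROIs outside the configured ROI set")
      }
      if (anyDuplicated(names(eff))) fail(fld, "contains duplicated ROI labels")
    }
  }
  if (!is.null(cfg$covariate_effects)) {
    ce <- cfg$covariate_effects
    if (!is.list(ce) || is.null(names(ce)) || !all(names(ce) %in% roi_names) ||
        any(lengths(ce) != 2L)) {
      fail("covariate_effects", "must be a named list of length-2 effect pairs over configured ROIs")
    }
  }
  if (!all(cfg$skewed_tests %in% battery_tests(cfg$battery))) {
    fail("skewed_tests", "names tests outside the battery")
  }
  hp <- cfg$handedness_probs
  if (any(hp < 0) || abs(sum(hp) - 1) > 1e-8) {
    fail("handedness_probs", "must be a probability vector summing to 1")
  }
  invisible(cfg)
}

# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort with known latent structure
#'
#' Draws a cohort from the generative model described in [cohort_config()]:
#' subject-level test scores (with completion times for timed tests, and
#' gender/handedness covariates) plus ROI-level cortical thickness and
#' local gyrification tables in which a known subset of ROIs carries a true
#' g effect. Everything downstream can therefore be checked against ground
#' truth.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with
#' \describe{
#'   \item{latent_g}{numeric vector, the true standard-normal g.}
#'   \item{scores}{tibble: `subject_id`, `gender` (0/1), `handedness`
#'     (ordinal rank), one raw-score column per test and a `<test>_time`
#'     column (seconds) per timed test.}
#'   \item{ct, lgi}{tibbles: `subject_id`, `gender`, `handedness`, then one
#'     column per ROI; `attr(, "measure")` is `"CT"` / `"LGI"`.}
#'   \item{truth}{tibble with `roi`, `measure`, `beta`, `true_effect`.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 50, seed = 7))
#' dim(coh$ct)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    bat <- config$battery
    tests <- battery_tests(bat)
    subject_id <- sprintf("S%03d", seq_len(n))

    lr <- config$loading_range
    loadings <- stats::setNames(stats::runif(length(tests), lr[1], lr[2]), tests)

    g <- stats::rnorm(n)
    domain_u <- matrix(stats::rnorm(n * length(bat$domains)), n,
                       dimnames = list(NULL, names(bat$domains)))

    latent <- matrix(NA_real_, n, length(tests), dimnames = list(NULL, tests))
    for (d in names(bat$domains)) {
      for (tst in bat$domains[[d]]) {
        latent[, tst] <- loadings[tst] * g +
          config$domain_noise_sd * domain_u[, d] +
          config$test_noise_sd * stats::rnorm(n)
      }
    }

    observed <- latent
    for (tst in config$skewed_tests) observed[, tst] <- exp(latent[, tst])

    scores <- tibble::tibble(subject_id = subject_id)
    times <- list()
    for (tst in tests) {
      if (tst %in% bat$timed_tests) {
        tm <- stats::rlnorm(n, meanlog = log(120), sdlog = 0.3)
        times[[paste0(tst, "_time")]] <- tm
        scores[[tst]] <- observed[, tst] * tm
      } else {
        scores[[tst]] <- observed[, tst]
      }
    }
    for (nm in names(times)) scores[[nm]] <- times[[nm]]

    gender <- sample(rep_len(c(0L, 1L), n))
    hand <- sample(seq_along(config$handedness_probs), n,
                   replace = TRUE, prob = config$handedness_probs)
    scores$gender <- gender
    scores$handedness <- hand

    cov_eff <- function(roi) {
      if (is.null(config$covariate_effects)) return(c(0.1, 0.05))
      ce <- config$covariate_effects[[roi]]
      if (is.null(ce)) c(0, 0) else as.numeric(ce)
    }
    make_measure <- function(effects, label) {
      tab <- tibble::tibble(subject_id = subject_id,
                            gender = gender, handedness = hand)
      for (roi in config$rois$roi) {
        beta <- if (roi %in% names(effects)) effects[[roi]] else 0
        gam <- cov_eff(roi)
        tab[[roi]] <- beta * g + gam[1] * gender + gam[2] * hand + stats::rnorm(n)
      }
      attr(tab, "measure") <- label
      tab
    }
    ct <- make_measure(config$ct_effects, "CT")
    lgi <- make_measure(config$lgi_effects, "LGI")

    truth <- dplyr::bind_rows(
      tibble::tibble(
        roi = config$rois$roi, measure = "CT",
        beta = ifelse(config$rois$roi %in% names(config$ct_effects),
                      config$ct_effects[config$rois$roi], 0)
      ),
      tibble::tibble(
        roi = config$rois$roi, measure = "LGI",
        beta = ifelse(config$rois$roi %in% names(config$lgi_effects),
                      config$lgi_effects[config$rois$roi], 0)
      )
    )
    truth$beta[is.na(truth$beta)] <- 0
    truth$true_effect <- truth$beta != 0

    structure(
      list(latent_g = g, scores = scores, ct = ct, lgi = lgi,
           loadings = loadings, truth = truth, config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", length(x$latent_g),
      "|", length(battery_tests(x$config$battery)), "tests |",
      nrow(x$config$rois), "ROIs per measure |",
      sum(x$truth$true_effect), "true ROI effects | seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the score table and both morphometry tables as headered CSV files
#' (wide layout: first column the subject id, one column per ROI) and a
#' JSON sidecar recording the ground truth, the generator parameters and
#' the seed, so a run can be reproduced exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    scores = file.path(dir, "scores.csv"),
    ct     = file.path(dir, "ct.csv"),
    lgi    = file.path(dir, "lgi.csv"),
    sidecar = file.path(dir, "cohort.json")
  )
  utils::write.csv(cohort$scores, paths[["scores"]], row.names = FALSE)
  utils::write.csv(cohort$ct, paths[["ct"]], row.names = FALSE)
  utils::write.csv(cohort$lgi, paths[["lgi"]], row.names = FALSE)
  cfg <- cohort$config
  sidecar <- list(
    seed = cfg$seed, n_subjects = cfg$n_subjects,
    gender_coding = "0 = reference group, 1 = comparison group; balanced",
    handedness = "ordinal rank, 1..K, higher = more right-handed",
    loading_range = cfg$loading_range,
    domain_noise_sd = cfg$domain_noise_sd, test_noise_sd = cfg$test_noise_sd,
    skewed_tests = cfg$skewed_tests,
    ct_effects = as.list(cfg$ct_effects), lgi_effects = as.list(cfg$lgi_effects),
    truth = cohort$truth
  )
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
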