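#' Define a cognitive test battery
#'
#' A battery maps cognitive domains to the tests that measure them, and
#' records per-test metadata that drives downstream conditioning: whether a
#' test is timed (its score is converted to an efficiency, score per unit
#' time, before anything else) and whether a higher score means better
#' performance.
#'
#' @param domains Named list; each element is a character vector of test
#'   names belonging to that domain. Domain order and within-domain test
#'   order are preserved and determine the deterministic enumeration order
#'   of test combinations.
#' @param timed_tests Character vector of test names whose raw scores are
#'   accompanied by a completion time and are time-weighted during
#'   conditioning. Must be a subset of the battery's tests.
#' @param higher_is_better Named logical vector giving, for tests where the
#'   natural direction is reversed (e.g. interference scores where lower is
#'   better), the direction flag. Tests not named here default to `TRUE`.
#'
#' @return An object of class `battery`: a list with elements `domains`,
#'   `timed_tests` and `direction` (named logical over all tests).
#' @examples
#' battery(
#'   domains = list(exec = c("trails", "stroop"), verbal = "vocab"),
#'   timed_tests = c("trails", "stroop")
#' )
#' @seealso [default_battery()] for the nine-test, four-domain battery the
#'   package uses as its reference configuration.
#' @export
battery <- function(domains, timed_tests = character(), higher_is_better = NULL) {
  if (!is.list(domains) || length(domains) < 1L || is.null(names(domains)) ||
      any(!nzchar(names(domains)))) {
    stop("`domains` must be a named list of character vectors", call. = FALSE)
  }
  domains <- lapply(domains, as.character)
  if (any(lengths(domains) < 1L)) {
    stop("every domain must contain at least one test", call. = FALSE)
  }
  tests <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(tests)) {
    stop("each test must belong to exactly one domain; duplicated: ",
         paste(unique(tests[duplicated(tests)]), collapse = ", "), call. = FALSE)
  }
  timed_tests <- as.character(timed_tests)
  if (!all(timed_tests %in% tests)) {
    stop("timed_tests not in the battery: ",
         paste(setdiff(timed_tests, tests), collapse = ", "), call. = FALSE)
  }
  direction <- stats::setNames(rep(TRUE, length(tests)), tests)
  if (!is.null(higher_is_better)) {
    if (is.null(names(higher_is_better)) ||
        !all(names(higher_is_better) %in% tests)) {
      stop("`higher_is_better` must be named by battery tests", call. = FALSE)
    }
    direction[names(higher_is_better)] <- as.logical(higher_is_better)
  }
  structure(
    list(domains = domains, timed_tests = timed_tests, direction = direction),
    class = "battery"
  )
}

#' The reference nine-test battery
#'
#' Four cognitive domains with 3/2/2/2 tests: executive function (modified
#' trail making, symbol digit modalities, Stroop), language (word puzzles,
#' comprehension), verbal fluency (phonemic F-A-S, category fluency) and
#' math/logic (mathematical puzzles, logical reasoning). The five speeded
#' tests (trail making, symbol digit, Stroop, math, logic) are timed. This
#' battery yields 3 x 2 x 2 x 2 = 24 one-test-per-domain combinations.
#'
#' @return A [battery()] object.
#' @export
default_battery <- function() {
  battery(
    domains = list(
      executive  = c("trail_making", "symbol_digit", "stroop"),
      language   = c("word_puzzles", "comprehension"),
      fluency    = c("fas_test", "category_fluency"),
      math_logic = c("math_puzzles", "logical_reasoning")
    ),
    timed_tests = c("trail_making", "symbol_digit", "stroop",
                    "math_puzzles", "logical_reasoning")
  )
}

#' @export
print.battery <- function(x, ...) {
  cat("<battery> ", length(battery_tests(x)), " tests in ",
      length(x$domains), " domains\n", sep = "")
  for (d in names(x$domains)) {
    cat("  ", d, ": ", paste(x$domains[[d]], collapse = ", "), "\n", sep = "")
  }
  if (length(x$timed_tests)) {
    cat("  timed: ", paste(x$timed_tests, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' All tests in a battery
#'
#' @param battery A [battery()] object.
#' @return Character vector of test names in domain order.
#' @export
battery_tests <- function(battery) {
  stopifnot(inherits(battery, "battery"))
  unlist(battery$domains, use.names = FALSE)
}
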