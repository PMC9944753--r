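#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rnorm runif rbinom rpois rexp var sd median
#'   coef predict glm binomial quantile as.formula model.matrix complete.cases
#'   pnorm dnorm optimize setNames
#' @importFrom rlang abort warn .data
#' @importFrom utils head tail write.csv read.csv
#' @importFrom grDevices pdf dev.off
NULL

# Day index 0 == 1990-01-01; 365.25-day years, "12 months" == 365 days.
DAYS_PER_YEAR <- 365.25
EXPOSURE_PERIOD_DAYS <- 365L
FOLLOWUP_END_DAY <- 3650L

expit <- stats::plogis
logit <- stats::qlogis

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions never clobber the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed derivation (Lehmer step + offset), kept inside 32-bit
# integer range; doubles are exact here (< 2^53).
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.numeric(k)) %% 2147483647)
}

#' Percentage of a count, rounded to one decimal
#'
#' The convention used in cohort summary tables: `100 * count / total`
#' rounded to one decimal place.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @return Numeric percentage rounded to 1 decimal.
#' @export
#' @examples
#' cohort_percent(33, 99)
cohort_percent <- function(count, total) {
  stopifnot(total > 0)
  round(100 * count / total, 1)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
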