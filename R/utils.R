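#' Logit and inverse-logit transforms
#'
#' Mortality probabilities are modelled on the logit scale throughout;
#' these helpers are exported because estimator output and smoother input
#' move between scales at the package boundary.
#'
#' @param p probability in (0, 1).
#' @param x real number.
#' @return `logit()` returns log(p / (1 - p)); `invlogit()` its inverse.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

## Calendar time is discretized to months: month index m corresponds to
## calendar year m %/% 12, month (m %% 12) + 1. Ages are month differences.

#' Month index helpers
#'
#' Time is discretized to calendar months. `month_index(y, m)` maps calendar
#' year `y`, month-of-year `m` (1-12) to an integer index; `year_of_month()`
#' inverts to the calendar year.
#'
#' @param year integer calendar year.
#' @param month integer month of year, 1-12.
#' @param m integer month index.
#' @return integer vector.
#' @export
month_index <- function(year, month = 7L) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer(year) * 12L + as.integer(month) - 1L
}

#' @rdname month_index
#' @export
year_of_month <- function(m) as.integer(m) %/% 12L

## internal: scalar check
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)

## internal: run expr with a private RNG stream derived from `seed`,
## restoring the caller's RNG state afterwards (keeps package functions
## deterministic-given-seed without clobbering the session RNG).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

## internal: derive a sub-seed below 2^31 from a base seed and an offset
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% 2147483587)
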