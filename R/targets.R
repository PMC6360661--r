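#' Annual rate of reduction (ARR)
#'
#' Assuming an exponential change between two time points, the discrete
#' compounding form is
#' \deqn{ARR = 1 - (U5M_{end} / U5M_{start})^{1/n},}
#' negative when mortality rises. The continuous form
#' `log(start/end) / n` is available via `form = "log"`.
#'
#' @param u5m_start,u5m_end positive mortality rates (any common scale).
#' @param n_years positive integer number of years between the two points.
#' @param form `"discrete"` (default) or `"log"`.
#' @return annual reduction as a fraction per year.
#' @examples
#' arr(99.3, 54.5, 13)  # ~0.045, i.e. 4.5% per year
#' @export
arr <- function(u5m_start, u5m_end, n_years, form = c("discrete", "log")) {
  form <- match.arg(form)
  if (any(u5m_start <= 0) || any(u5m_end <= 0))
    stop("mortality rates must be positive")
  if (!is_count(n_years)) stop("n_years must be a positive integer")
  if (form == "discrete") 1 - (u5m_end / u5m_start)^(1 / n_years)
  else log(u5m_start / u5m_end) / n_years
}

#' Project a mortality rate forward at a constant ARR
#'
#' `project_u5m(a, arr(a, b, n), n)` returns `b` exactly (round-trip
#' identity).
#'
#' @param u5m positive starting rate.
#' @param arr_value annual rate of reduction (fraction; must be < 1).
#' @param n_years number of years to project.
#' @return projected rate `u5m * (1 - arr_value)^n_years`.
#' @export
project_u5m <- function(u5m, arr_value, n_years) {
  if (any(u5m <= 0)) stop("u5m must be positive")
  if (any(arr_value >= 1)) stop("arr_value must be below 1")
  u5m * (1 - arr_value)^n_years
}

#' Assess mortality-reduction targets for one county series
#'
#' Applies three global goals to a county's posterior-mean U5M series (per
#' 1000 live births):
#' \itemize{
#'   \item World Summit for Children (WSC): U5M of at most 70 by 2000 OR a
#'     one-third reduction between 1990 and 2000.
#'   \item MDG 4: two-thirds reduction between 1990 and 2015, with the 2015
#'     value projected from the 2000-2013 ARR.
#'   \item SDG 3.2: U5M of at most 25 by 2030, evaluated only when a 2030
#'     value is supplied.
#' }
#' `margin_class` is `"achieved"`, `"near_miss"` when the binding criterion
#' of the earliest missed goal is missed by at most 20% (relative), else
#' `"missed"`.
#'
#' @param series data.frame with columns `year` and `u5m` (per 1000)
#'   covering at least 1990-2013, plus optional `county_id`.
#' @param arr_window years used for the projection ARR (default
#'   `c(2000, 2013)`).
#' @param u5m_2030 optional projected/assumed 2030 rate for the SDG check.
#' @return one-row data.frame: `county_id`, `u5m_1990`, `u5m_2000`,
#'   `u5m_2013`, `u5m_2015_projected`, `arr_2000_2013`, `wsc_achieved`,
#'   `mdg4_achieved`, `sdg_achieved` (NA unless `u5m_2030` given),
#'   `margin_class`.
#' @export
assess_targets <- function(series, arr_window = c(2000, 2013),
                           u5m_2030 = NULL) {
  need <- c(1990, 2000, arr_window, 2013)
  at <- function(yr) {
    i <- match(yr, series$year)
    if (is.na(i)) stop("series is missing required year ", yr)
    series$u5m[i]
  }
  for (yr in need) at(yr)
  u90 <- at(1990); u00 <- at(2000); u13 <- at(2013)
  a <- arr(at(arr_window[1L]), at(arr_window[2L]),
           arr_window[2L] - arr_window[1L])
  u15 <- project_u5m(u13, a, 2015L - 2013L)

  wsc <- u00 <= 70 || (1 - u00 / u90) >= 1 / 3
  mdg4 <- (1 - u15 / u90) >= 2 / 3
  sdg <- if (is.null(u5m_2030)) NA else u5m_2030 <= 25

  ## relative closeness to the binding criterion of the first missed goal
  margin <- if (!wsc) {
    min((u00 - 70) / 70, (u00 / u90 - 2 / 3) / (2 / 3))
  } else if (!mdg4) {
    (u15 / u90 - 1 / 3) / (1 / 3)
  } else NA_real_
  margin_class <- if (wsc && mdg4) "achieved"
  else if (margin <= 0.20) "near_miss" else "missed"

  data.frame(county_id = series$county_id[1L] %||% NA_character_,
             u5m_1990 = u90, u5m_2000 = u00, u5m_2013 = u13,
             u5m_2015_projected = u15, arr_2000_2013 = a,
             wsc_achieved = wsc, mdg4_achieved = mdg4, sdg_achieved = sdg,
             margin_class = margin_class, stringsAsFactors = FALSE)
}

#' Palma-adapted between-county inequality ratio
#'
#' Mean U5M of the worst-off 40% of counties divided by the mean U5M of the
#' best-off 10%, for one year. Group sizes round to the nearest integer
#' (47 counties give 19 high and 5 low). The ratio is scale-invariant and
#' at least 1.
#'
#' @param values positive per-county rates for one year (length >= 10).
#' @param high,low the quantile fractions defining the two groups.
#' @return the inequality ratio (>= 1 whenever high-group rates dominate).
#' @examples
#' inequality_ratio(seq(10, 100, by = 10))  # 8.5
#' @export
inequality_ratio <- function(values, high = 0.40, low = 0.10) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 10L) stop("need at least 10 counties for the 40/10 ratio")
  if (any(values <= 0)) stop("rates must be positive")
  n_high <- max(1L, round(high * k))
  n_low <- max(1L, round(low * k))
  s <- sort(values, decreasing = TRUE)
  mean(s[seq_len(n_high)]) / mean(s[k - seq_len(n_low) + 1L])
}

#' Target assessment and inequality for a whole posterior surface
#'
#' @param summaries posterior summary data.frame from
#'   [summarize_posterior()] (`county_id`, `year`, `mean` per 1000).
#' @param arr_window years used for the projection ARR.
#' @return list with `assessment` (one row per county, see
#'   [assess_targets()]) and `inequality` (per-year 40/10 ratio; NA for
#'   years with fewer than 10 counties).
#' @export
assess_surface <- function(summaries, arr_window = c(2000, 2013)) {
  counties <- unique(summaries$county_id)
  assessment <- do.call(rbind, lapply(counties, function(cty) {
    s <- summaries[summaries$county_id == cty, ]
    assess_targets(data.frame(county_id = cty, year = s$year, u5m = s$mean),
                   arr_window = arr_window)
  }))
  years <- sort(unique(summaries$year))
  ineq <- vapply(years, function(yr) {
    v <- summaries$mean[summaries$year == yr]
    if (length(v) >= 10L) inequality_ratio(v) else NA_real_
  }, 0)
  list(assessment = assessment,
       inequality = data.frame(year = years, ratio = ineq))
}
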