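#' Tabulate under-five deaths and exposure by age segment and period
#'
#' Allocates each child's lived months to the six age segments (month 0,
#' months 1-11, years 1, 2, 3, 4) and to consecutive calendar periods
#' (default two years wide) counted backwards from the interview month.
#' A child contributes one month of exposure for every completed month lived
#' under age five and observed before the interview; the death month
#' contributes a full month of exposure plus one death in the segment
#' containing `death_age_months` and the period containing the death's
#' calendar month.
#'
#' When records pool several interview dates the periods are anchored at the
#' latest interview month present; each child is still censored at its own
#' interview.
#'
#' @param records a `u5m_cbh`.
#' @param period_months period width in months (default 24).
#' @return an `exposure_table`: list with `D` and `E` (6 x P matrices of
#'   deaths and exposure in child-months), `periods` (data.frame with
#'   `period`, most recent = 0, and `midpoint_year`), `n_women`,
#'   `n_children`.
#' @export
tabulate_exposure <- function(records, period_months = 24L) {
  stopifnot(inherits(records, "u5m_cbh"))
  if (!is_count(period_months)) stop("period_months must be a positive integer")
  ch <- records$children
  if (nrow(ch) == 0L) stop("no child records to tabulate")
  bad <- which(!is.na(ch$death_age_months) &
                 (ch$death_age_months > 59L | ch$death_age_months < 0L))
  if (length(bad))
    stop("death_age_months outside 0-59 for child record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  anchor <- max(ch$interview_month)
  dead <- !is.na(ch$death_age_months)
  ## last observed age month per child
  last <- ifelse(dead, ch$death_age_months,
                 pmin(59L, ch$interview_month - ch$birth_month))
  n_m <- last + 1L
  child <- rep.int(seq_len(nrow(ch)), n_m)
  age_m <- sequence(n_m) - 1L
  cal_m <- ch$birth_month[child] + age_m
  seg <- findInterval(age_m, SEG_START)
  per <- (anchor - cal_m) %/% period_months
  n_per <- max(per) + 1L
  E <- matrix(0, 6L, n_per)
  idx <- (per) * 6L + seg  # 1-based within flattened 6 x n_per
  tabE <- tabulate(idx, nbins = 6L * n_per)
  E[] <- tabE
  D <- matrix(0, 6L, n_per)
  if (any(dead)) {
    d_age <- ch$death_age_months[dead]
    d_cal <- ch$birth_month[dead] + d_age
    d_idx <- ((anchor - d_cal) %/% period_months) * 6L + findInterval(d_age, SEG_START)
    D[] <- tabulate(d_idx, nbins = 6L * n_per)
  }
  mid <- anchor - period_months * (seq_len(n_per) - 1L) - period_months %/% 2L
  structure(list(D = D, E = E,
                 periods = data.frame(period = seq_len(n_per) - 1L,
                                      midpoint_year = year_of_month(mid)),
                 period_months = as.integer(period_months),
                 n_women = nrow(records$women), n_children = nrow(ch)),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat("exposure_table:", ncol(x$E), "periods x 6 age segments;",
      sum(x$D), "deaths /", sum(x$E), "child-months\n")
  invisible(x)
}

#' Direct (synthetic-cohort) under-five mortality per period
#'
#' For each period, the monthly death probability in age segment s is
#' `m_s = D_s / E_s`; the probability of surviving the segment is
#' `(1 - m_s)^w_s` with w the segment width in months, and
#' \deqn{q_5 = 1 - \prod_s (1 - m_s)^{w_s}.}
#' A period in which any segment has zero exposure is flagged undefined
#' (`q5 = NA`) rather than silently reported as 0.
#'
#' @param table an `exposure_table` from [tabulate_exposure()].
#' @return data.frame with one row per period: `period`, `year` (midpoint
#'   calendar year), `q5`, `deaths`, `exposure_months`, `defined`.
#' @export
q5_direct <- function(table) {
  stopifnot(inherits(table, "exposure_table"))
  w <- SEG_WIDTH
  P <- ncol(table$E)
  q5 <- rep(NA_real_, P)
  defined <- colSums(table$E == 0) == 0L
  for (p in which(defined)) {
    m <- table$D[, p] / table$E[, p]
    q5[p] <- 1 - prod((1 - m)^w)
  }
  data.frame(period = table$periods$period, year = table$periods$midpoint_year,
             q5 = q5, deaths = colSums(table$D),
             exposure_months = colSums(table$E), defined = defined)
}

#' Direct estimates by county (or pooled) from complete birth histories
#'
#' Convenience wrapper running [tabulate_exposure()] and [q5_direct()]
#' within each county, returning rows in the estimates schema consumed by
#' the spatio-temporal smoother. Undefined periods are dropped.
#'
#' @param records a `u5m_cbh`.
#' @param period_months period width in months.
#' @param by_county per-county (default) or pooled ("national") series.
#' @param min_deaths periods with fewer observed deaths are dropped (they
#'   carry no information about the level and produce boundary estimates);
#'   default 1.
#' @param max_years_back periods whose midpoint lies further before the
#'   interview are dropped (default 25): in old periods only the children of
#'   women still aged under 50 are observed, so the estimates grow
#'   increasingly selective as well as sparse.
#' @return data.frame: `survey_id`, `method` ("direct"), `county_id`,
#'   `year`, `q5`, `n` (women contributing).
#' @export
estimate_direct <- function(records, period_months = 24L, by_county = TRUE,
                            min_deaths = 1L, max_years_back = 25) {
  stopifnot(inherits(records, "u5m_cbh"))
  min_year <- year_of_month(max(records$children$interview_month)) - max_years_back
  split_cty <- if (by_county) unique(records$women$county_id) else "all"
  out <- lapply(split_cty, function(cty) {
    sub <- if (by_county) subset_cbh(records, cty) else records
    if (nrow(sub$children) == 0L) return(NULL)
    est <- q5_direct(tabulate_exposure(sub, period_months))
    est <- est[est$defined & est$deaths >= min_deaths & est$q5 > 0 &
                 est$q5 < 1 & est$year >= min_year, ]
    if (nrow(est) == 0L) return(NULL)
    data.frame(survey_id = records$survey_id %||% "cbh",
               method = "direct", county_id = cty, year = est$year,
               q5 = est$q5, n = nrow(sub$women), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: restrict a u5m_cbh to one county
subset_cbh <- function(records, county) {
  structure(list(women = records$women[records$women$county_id == county, ,
                                       drop = FALSE],
                 children = records$children[records$children$county_id == county, ,
                                             drop = FALSE],
                 survey_id = records$survey_id,
                 interview_month = records$interview_month),
            class = "u5m_cbh")
}
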