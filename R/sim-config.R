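#' Simulation configuration
#'
#' Bundles every parameter of the synthetic birth-history generator: the
#' latent mortality surface (intercept and spatio-temporal field), the
#' age pattern of under-five deaths, age-specific fertility, and the survey
#' schedule. Defaults emulate a high-fertility, declining-mortality setting
#' observed through a handful of heterogeneous surveys.
#'
#' @param graph a [u5m_graph] of counties.
#' @param year_range inclusive calendar years `c(t_min, t_max)` covered by
#'   the true surface.
#' @param alpha intercept of U5M on the logit scale (default -2.2, i.e.
#'   about 100 deaths per 1000 live births).
#' @param sigma2_S marginal variance of the spatio-temporal deviations on
#'   the logit scale (>= 0).
#' @param rho_s spatial CAR dependence in [0, 1).
#' @param phi_t temporal AR(1) coefficient in (-1, 1).
#' @param tau2_by_method named vector of method-specific noise factors (used
#'   when simulating observation-level estimates directly from the model).
#' @param hazard_split six non-negative weights summing to 1 that allocate
#'   under-five deaths across the age segments month 0, months 1-11 and
#'   years 1-4; the default declining pattern loosely mimics model life
#'   tables.
#' @param fertility_rates named vector of annual birth probabilities for the
#'   seven 5-year maternal age groups 15-19, ..., 45-49.
#' @param surveys list of survey specifications from [survey_spec()].
#' @param seed integer seed governing every draw of the generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(graph,
                       year_range,
                       alpha = -2.2,
                       sigma2_S = 0.2,
                       rho_s = 0.9,
                       phi_t = 0.9,
                       tau2_by_method = c(direct = 0.2, cohort_MA = 0.5,
                                          cohort_TFB = 0.5, period_MA = 0.4,
                                          period_TFB = 0.4),
                       hazard_split = c(0.35, 0.30, 0.15, 0.10, 0.06, 0.04),
                       fertility_rates = c(`15-19` = 0.10, `20-24` = 0.25,
                                           `25-29` = 0.26, `30-34` = 0.22,
                                           `35-39` = 0.16, `40-44` = 0.08,
                                           `45-49` = 0.03),
                       surveys = list(),
                       seed = 1L) {
  stopifnot(inherits(graph, "u5m_graph"))
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[2L] < year_range[1L])
    stop("year_range must be c(t_min, t_max) with t_max >= t_min")
  if (!is.numeric(sigma2_S) || sigma2_S < 0) stop("sigma2_S must be >= 0")
  if (rho_s < 0 || rho_s >= 1) stop("rho_s must lie in [0, 1)")
  if (abs(phi_t) >= 1) stop("phi_t must lie in (-1, 1)")
  if (length(hazard_split) != 6L || any(hazard_split < 0) ||
      abs(sum(hazard_split) - 1) > 1e-8)
    stop("hazard_split must be 6 non-negative weights summing to 1")
  if (length(fertility_rates) != 7L || any(fertility_rates < 0) ||
      any(fertility_rates >= 1))
    stop("fertility_rates must be 7 annual probabilities in [0, 1)")
  for (s in surveys) {
    if (!inherits(s, "u5m_survey_spec")) stop("surveys must come from survey_spec()")
    if (s$year < year_range[1L])
      stop("survey year ", s$year, " precedes year_range")
    if (!all(s$counties %in% graph$nodes))
      stop("survey covers counties absent from the graph")
  }
  structure(list(graph = graph, K = length(graph$nodes),
                 year_range = year_range, alpha = alpha, sigma2_S = sigma2_S,
                 rho_s = rho_s, phi_t = phi_t,
                 tau2_by_method = tau2_by_method,
                 hazard_split = hazard_split,
                 fertility_rates = fertility_rates,
                 surveys = surveys, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$K, "counties, years", x$year_range[1L], "-",
      x$year_range[2L], ",", length(x$surveys), "surveys, seed", x$seed, "\n")
  invisible(x)
}

#' Survey specification
#'
#' One entry of a simulated data-collection schedule: a household survey or
#' census interviewing `women` women aged 15-49 in each listed county in a
#' given calendar year. Censuses are represented as SBH-only surveys with
#' very large `women`.
#'
#' @param year calendar year of interview.
#' @param counties character vector of covered county ids.
#' @param women number of women interviewed per county.
#' @param collects_cbh,collects_sbh which birth-history instruments the
#'   source collects.
#' @param id optional survey label; defaults to `"svy<year>"`.
#' @return an object of class `u5m_survey_spec`.
#' @export
survey_spec <- function(year, counties, women, collects_cbh = TRUE,
                        collects_sbh = TRUE, id = NULL) {
  if (!is_count(women)) stop("women must be a positive integer")
  if (!collects_cbh && !collects_sbh) stop("survey must collect CBH or SBH")
  structure(list(id = if (is.null(id)) paste0("svy", year) else as.character(id),
                 year = as.integer(year), counties = as.character(counties),
                 women = as.integer(women),
                 collects_cbh = isTRUE(collects_cbh),
                 collects_sbh = isTRUE(collects_sbh)),
            class = "u5m_survey_spec")
}
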