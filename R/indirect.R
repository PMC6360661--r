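#' Parity ratios from a maternal-age SBH table
#'
#' Average parities P(g) = CEB_g / W_g for the three youngest maternal-age
#' groups proxy the timing of childbearing in the cohort regression. Returns
#' the two ratios P(15-19)/P(20-24) and P(20-24)/P(25-29).
#'
#' @param sbh an `sbh_table` with maternal-age grouping (rows for a single
#'   county or pooled).
#' @return numeric vector `c(ratio_1, ratio_2)`.
#' @export
parity_ratios <- function(sbh) {
  if (!identical(attr(sbh, "grouping"), "MA"))
    stop("parity ratios require the maternal-age grouping")
  need <- c("15-19", "20-24", "25-29")
  rows <- match(need, sbh$group_label)
  if (anyNA(rows)) stop("groups 15-19, 20-24, 25-29 must be present")
  if (any(sbh$women[rows] <= 0)) stop("zero women in a parity group")
  p <- sbh$ceb[rows] / sbh$women[rows]
  if (any(p[2:3] == 0)) stop("undefined parity ratio: zero denominator parity")
  c(ratio_1 = p[1L] / p[2L], ratio_2 = p[2L] / p[3L])
}

#' Cohort indirect under-five mortality
#'
#' Brass-type cohort conversion: for each 5-year group i with children dead
#' CD_i and children ever born CEB_i,
#' \deqn{logit(q_5) = \beta_{0i} + U + \beta_{1i} logit(CD_i/CEB_i) +
#'   \beta_{2i} \bar{CEB}_i + \beta_{3i} r_1 + \beta_{4i} r_2,}
#' where \eqn{\bar{CEB}_i} is the mean number of children ever born per
#' woman in the group and r_1, r_2 the parity ratios. Each group's estimate
#' refers to `ref_offset` years before the interview. Groups with CD = 0 or
#' CD = CEB carry no usable signal and are skipped (with a message).
#'
#' @param sbh an `sbh_table` restricted to one county (or pooled).
#' @param coeffs a `cohort_coefficients` table whose grouping matches `sbh`.
#' @param ratios parity ratios from [parity_ratios()].
#' @return data.frame: `group_label`, `q5`, `reference_year` (fractional),
#'   `women`.
#' @export
cohort_q5 <- function(sbh, coeffs, ratios) {
  stopifnot(inherits(coeffs, "cohort_coefficients"))
  if (!identical(attr(sbh, "grouping"), attr(coeffs, "grouping")))
    stop("grouping of coefficients (", attr(coeffs, "grouping"),
         ") does not match SBH table (", attr(sbh, "grouping"), ")")
  iy <- attr(sbh, "interview_year")
  usable <- sbh$women > 0 & sbh$ceb > 0 & sbh$cd > 0 & sbh$cd < sbh$ceb
  skipped <- sbh$group_label[sbh$ceb > 0 & !usable]
  if (length(skipped))
    message("cohort_q5: skipping group(s) without usable CD/CEB: ",
            paste(skipped, collapse = ", "))
  sub <- sbh[usable, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(group_label = character(), q5 = numeric(),
                      reference_year = numeric(), women = integer()))
  j <- match(sub$group_label, coeffs$group_label)
  if (anyNA(j))
    stop("missing coefficient row for populated group(s): ",
         paste(sub$group_label[is.na(j)], collapse = ", "))
  ceb_bar <- sub$ceb / sub$women
  lg <- coeffs$beta0[j] + coeffs$u[j] +
    coeffs$beta1[j] * logit(sub$cd / sub$ceb) +
    coeffs$beta2[j] * ceb_bar +
    coeffs$beta3[j] * ratios[[1L]] + coeffs$beta4[j] * ratios[[2L]]
  data.frame(group_label = sub$group_label, q5 = invlogit(lg),
             reference_year = iy - coeffs$ref_offset[j], women = sub$women)
}

#' Redistribute SBH totals over years before the survey
#'
#' Period indirect methods first spread each group's reported children ever
#' born and children dead over single years before the survey using
#' empirical distributions of births and of deaths (the latter indexed by
#' the dead child's year of birth):
#' `CEB_t = sum_g CEB_g * birth_p(g, t)` and likewise for CD. Totals are
#' conserved exactly.
#'
#' @param sbh an `sbh_table` restricted to one county (or pooled).
#' @param dist an `empirical_distribution` whose grouping matches `sbh`.
#' @return data.frame: `years_before`, `ceb`, `cd`.
#' @export
period_redistribute <- function(sbh, dist) {
  stopifnot(inherits(dist, "empirical_distribution"))
  if (!identical(attr(sbh, "grouping"), attr(dist, "grouping")))
    stop("grouping of distribution does not match SBH table")
  groups <- unique(dist$group_label)
  for (g in groups) {
    d <- dist[dist$group_label == g, ]
    if (abs(sum(d$birth_p) - 1) > 1e-9 || abs(sum(d$death_p) - 1) > 1e-9)
      stop("empirical distribution for group ", g, " does not sum to 1")
  }
  horizon <- sort(unique(dist$years_before))
  ceb_t <- cd_t <- numeric(length(horizon))
  for (i in seq_len(nrow(sbh))) {
    g <- sbh$group_label[i]
    if (!g %in% groups) {
      if (sbh$ceb[i] > 0) stop("no empirical distribution for populated group ", g)
      next
    }
    d <- dist[dist$group_label == g, ]
    j <- match(d$years_before, horizon)
    ceb_t[j] <- ceb_t[j] + sbh$ceb[i] * d$birth_p
    cd_t[j] <- cd_t[j] + sbh$cd[i] * d$death_p
  }
  data.frame(years_before = horizon, ceb = ceb_t, cd = cd_t)
}

#' Period indirect under-five mortality
#'
#' Converts redistributed per-year proportions dead to U5M:
#' \deqn{logit(q_{5,t}) = \beta^0_t + U_t + \beta^1_t logit(CD_t/CEB_t).}
#' Years with no births, no deaths, all dead, or beyond the coefficient
#' horizon (at most 25 years before the survey) are dropped.
#'
#' @param per_year output of [period_redistribute()].
#' @param coeffs a `period_coefficients` table.
#' @param interview_year calendar year of the survey.
#' @return data.frame: `years_before`, `q5`, `year`, `ceb`.
#' @export
period_q5 <- function(per_year, coeffs, interview_year) {
  stopifnot(inherits(coeffs, "period_coefficients"))
  j <- match(per_year$years_before, coeffs$years_before)
  ok <- !is.na(j) & per_year$ceb > 0 & per_year$cd > 0 & per_year$cd < per_year$ceb
  sub <- per_year[ok, , drop = FALSE]
  jj <- j[ok]
  if (nrow(sub) == 0L)
    return(data.frame(years_before = integer(), q5 = numeric(),
                      year = integer(), ceb = numeric()))
  lg <- coeffs$beta0[jj] + coeffs$u[jj] +
    coeffs$beta1[jj] * logit(sub$cd / sub$ceb)
  data.frame(years_before = sub$years_before, q5 = invlogit(lg),
             year = interview_year - sub$years_before, ceb = sub$ceb)
}

#' Indirect estimates in the smoother's observation schema
#'
#' Applies the cohort and period conversions to every county of an SBH
#' table, labelling methods `cohort_MA` / `period_MA` or `cohort_TFB` /
#' `period_TFB` according to the table's grouping. Cohort reference years
#' are rounded to calendar years.
#'
#' @param sbh an `sbh_table` (per-county rows).
#' @param coeffs a coefficient bundle from [calibrate_coefficients()] or
#'   [default_coefficients()].
#' @param survey_id label copied into the output.
#' @return data.frame: `survey_id`, `method`, `county_id`, `year`, `q5`, `n`.
#' @export
estimate_indirect <- function(sbh, coeffs, survey_id = "sbh") {
  stopifnot(inherits(coeffs, "u5m_coefficients"))
  grouping <- attr(sbh, "grouping")
  iy <- attr(sbh, "interview_year")
  cc <- coeffs[[paste0("cohort_", grouping)]]
  pc <- coeffs[[paste0("period_", grouping)]]
  dd <- coeffs[[paste0("dist_", grouping)]]
  out <- list()
  for (cty in unique(sbh$county_id)) {
    tab <- sbh[sbh$county_id == cty, , drop = FALSE]
    attr(tab, "grouping") <- grouping
    attr(tab, "interview_year") <- iy
    n_cty <- sum(tab$women)
    ratios <- tryCatch(
      if (grouping == "MA") parity_ratios(tab) else c(ratio_1 = 1, ratio_2 = 1),
      error = function(e) NULL)
    if (!is.null(ratios)) {
      co <- suppressMessages(cohort_q5(tab, cc, ratios))
      if (nrow(co))
        out[[length(out) + 1L]] <- data.frame(
          survey_id = survey_id, method = paste0("cohort_", grouping),
          county_id = cty, year = as.integer(round(co$reference_year)),
          q5 = co$q5, n = n_cty, stringsAsFactors = FALSE)
    }
    pe <- period_q5(period_redistribute(tab, dd), pc, iy)
    if (nrow(pe))
      out[[length(out) + 1L]] <- data.frame(
        survey_id = survey_id, method = paste0("period_", grouping),
        county_id = cty, year = as.integer(pe$year), q5 = pe$q5, n = n_cty,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
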