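#' Simulate complete birth histories for one survey
#'
#' Generates the microdata one survey would collect: women aged uniformly
#' 15-49 at interview, live births produced month by month from the
#' age-specific fertility schedule, and each child's survival drawn from a
#' piecewise-constant monthly hazard over the six under-five age segments
#' (month 0, months 1-11, and the four single years 1-4). Segment hazards
#' are chosen so that a child born in county k and calendar year t dies
#' before age five with probability exactly `surface$Q[k, t]`, with the
#' share of those deaths in each segment given by `config$hazard_split`.
#' Deaths occurring after the interview month are censored and recorded as
#' alive; a death in the interview month itself counts as observed.
#'
#' @param config a [sim_config].
#' @param surface a `u5m_surface` from [sample_true_surface()].
#' @param survey_index which entry of `config$surveys` to realise.
#' @param seed optional seed; defaults to a stream derived from
#'   `config$seed` and `survey_index`, so each survey is reproducible in
#'   isolation.
#' @return an object of class `u5m_cbh`: list with data.frames `women`
#'   (woman_id, county_id, birth_month, interview_month) and `children`
#'   (woman_id, county_id, birth_month, death_age_months with NA = alive,
#'   interview_month), plus `survey_id` and `interview_month`.
#' @export
simulate_survey <- function(config, surface, survey_index, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(surface, "u5m_surface"))
  if (!is_count(survey_index) || survey_index > length(config$surveys))
    stop("survey_index out of range")
  survey <- config$surveys[[survey_index]]
  if (is.null(seed)) seed <- sub_seed(config$seed, survey_index)
  interview_month <- month_index(survey$year, 7L)

  with_seed(seed, {
    women_l <- vector("list", length(survey$counties))
    child_l <- vector("list", length(survey$counties))
    offset <- 0L
    for (ci in seq_along(survey$counties)) {
      cty <- survey$counties[ci]
      n <- survey$women
      age_months <- sample(180:599, n, replace = TRUE)  # uniform 15-49 yrs
      wid <- sprintf("%s_%s_w%06d", survey$id, cty, offset + seq_len(n))
      offset <- offset + n
      w_birth <- interview_month - age_months
      births <- sim_births(age_months, config$fertility_rates)
      women_l[[ci]] <- data.frame(woman_id = wid, county_id = cty,
                                  birth_month = w_birth,
                                  interview_month = interview_month,
                                  stringsAsFactors = FALSE)
      if (nrow(births)) {
        cb_month <- w_birth[births$woman] + births$age_month_at_birth
        q <- surface_q(surface, rep(cty, nrow(births)), year_of_month(cb_month))
        d_age <- sim_death_age(q, config$hazard_split)
        observed <- !is.na(d_age) & (cb_month + d_age <= interview_month)
        d_age[!observed] <- NA_integer_
        child_l[[ci]] <- data.frame(woman_id = wid[births$woman],
                                    county_id = cty, birth_month = cb_month,
                                    death_age_months = d_age,
                                    interview_month = interview_month,
                                    stringsAsFactors = FALSE)
      }
    }
    women <- do.call(rbind, women_l)
    children <- do.call(rbind, child_l)
    if (is.null(children))
      children <- data.frame(woman_id = character(), county_id = character(),
                             birth_month = integer(),
                             death_age_months = integer(),
                             interview_month = integer(),
                             stringsAsFactors = FALSE)
    rownames(women) <- rownames(children) <- NULL
    structure(list(women = women, children = children,
                   survey_id = survey$id, interview_month = interview_month),
              class = "u5m_cbh")
  })
}

#' @export
print.u5m_cbh <- function(x, ...) {
  cat("u5m_cbh", if (!is.null(x$survey_id)) paste0("(", x$survey_id, ")"),
      ":", nrow(x$women), "women,", nrow(x$children), "children,",
      sum(!is.na(x$children$death_age_months)), "observed deaths\n")
  invisible(x)
}

## internal: births per woman. age_months = age at interview; annual rates by
## 5-year maternal age group are converted to a constant monthly probability
## within the group. Month-level Bernoulli draws are collapsed to one
## binomial count per (woman, single-year age) cell, then birth months are
## placed uniformly within the cell - distributionally identical and much
## faster than a month loop. Returns data.frame(woman, age_month_at_birth).
sim_births <- function(age_months, fertility_rates) {
  n <- length(age_months)
  ages <- 15:49
  p_year <- fertility_rates[pmin((ages - 15L) %/% 5L + 1L, 7L)]
  p_month <- 1 - (1 - p_year)^(1 / 12)
  out_w <- integer(0); out_m <- integer(0)
  for (a in seq_along(ages)) {
    lo <- 12L * ages[a]
    ## months of age-year `a` observed before/at interview
    cnt <- pmax(0L, pmin(lo + 11L, age_months) - lo + 1L)
    nb <- stats::rbinom(n, cnt, p_month[a])
    has <- which(nb > 0L)
    if (!length(has)) next
    w <- rep.int(has, nb[has])
    u <- floor(stats::runif(length(w)) * rep.int(cnt[has], nb[has]))
    out_w <- c(out_w, w)
    out_m <- c(out_m, lo + as.integer(u))
  }
  data.frame(woman = out_w, age_month_at_birth = out_m)
}

## segment anatomy shared by generator and direct estimator
SEG_START <- c(0L, 1L, 12L, 24L, 36L, 48L)
SEG_WIDTH <- c(1L, 11L, 12L, 12L, 12L, 12L)

## internal: death age in months (NA = survives past 59 months) for children
## with under-five death probability q, deaths allocated to the six age
## segments by `split`, constant monthly hazard within each segment.
sim_death_age <- function(q, split) {
  n <- length(q)
  d_age <- rep(NA_integer_, n)
  dies <- stats::runif(n) < q
  nd <- sum(dies)
  if (nd == 0L) return(d_age)
  cum <- cumsum(split)
  seg <- findInterval(stats::runif(nd), cum, left.open = TRUE) + 1L
  seg <- pmin(seg, 6L)
  qd <- q[dies]
  ## within-segment monthly survival: segment s spans cumulative death shares
  ## (cum[s-1], cum[s]]; survival over the whole segment among those alive at
  ## its start is (1 - q*cum[s]) / (1 - q*cum[s-1])
  clo <- c(0, cum[-6L])[seg]
  chi <- cum[seg]
  p_seg <- ((1 - qd * chi) / (1 - qd * clo))^(1 / SEG_WIDTH[seg])
  ## truncated-geometric month offset within the segment
  u <- stats::runif(nd)
  j <- ifelse(SEG_WIDTH[seg] == 1L, 0,
              pmin(floor(log1p(-u * (1 - p_seg^SEG_WIDTH[seg])) / log(p_seg)),
                   SEG_WIDTH[seg] - 1L))
  d_age[dies] <- SEG_START[seg] + as.integer(j)
  d_age
}

#' Simulate every survey in a configuration
#'
#' @param config a [sim_config].
#' @param surface optional pre-drawn surface; sampled from `config` if
#'   missing.
#' @return list with `surface` and `surveys` (a list of `u5m_cbh`, one per
#'   entry of `config$surveys`).
#' @export
simulate_all_surveys <- function(config, surface = NULL) {
  if (is.null(surface)) surface <- sample_true_surface(config)
  surveys <- lapply(seq_along(config$surveys), function(i)
    simulate_survey(config, surface, i))
  list(surface = surface, surveys = surveys)
}
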