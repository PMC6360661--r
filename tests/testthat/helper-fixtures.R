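# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive per-child / per-month loops so they share no code with the
# vectorised implementation they check.

new_cbh <- function(women, children = NULL, survey_id = "fix") {
  if (is.null(children))
    children <- data.frame(woman_id = character(), county_id = character(),
                           birth_month = integer(),
                           death_age_months = integer(),
                           interview_month = integer(),
                           stringsAsFactors = FALSE)
  structure(list(women = women, children = children, survey_id = survey_id,
                 interview_month = max(women$interview_month)),
            class = "u5m_cbh")
}

# one woman aged `age_years` at interview, with children given as a list of
# (age_at_interview_months, death_age_months or NA)
fix_woman <- function(id, age_years, kids = list(), county = "C01",
                      interview_month = month_index(2010)) {
  w <- data.frame(woman_id = id, county_id = county,
                  birth_month = interview_month - age_years * 12L,
                  interview_month = interview_month,
                  stringsAsFactors = FALSE)
  ch <- NULL
  if (length(kids))
    ch <- data.frame(woman_id = id, county_id = county,
                     birth_month = interview_month -
                       vapply(kids, function(k) as.integer(k[[1L]]), 1L),
                     death_age_months = vapply(kids, function(k)
                       if (is.na(k[2L])) NA_integer_ else as.integer(k[2L]), 1L),
                     interview_month = interview_month,
                     stringsAsFactors = FALSE)
  list(women = w, children = ch)
}

bind_cbh <- function(...) {
  parts <- list(...)
  new_cbh(do.call(rbind, lapply(parts, `[[`, "women")),
          do.call(rbind, Filter(Negate(is.null),
                                lapply(parts, `[[`, "children"))))
}

# random child-level fixture for oracle comparisons
random_cbh <- function(n_children, seed, interview_month = month_index(2010)) {
  set.seed(seed)
  n_w <- ceiling(n_children / 3)
  women <- data.frame(
    woman_id = sprintf("w%04d", seq_len(n_w)), county_id = "C01",
    birth_month = interview_month - sample(180:599, n_w, replace = TRUE),
    interview_month = interview_month, stringsAsFactors = FALSE)
  wi <- sample(n_w, n_children, replace = TRUE)
  birth <- interview_month - sample(0:300, n_children, replace = TRUE)
  death <- ifelse(runif(n_children) < 0.25,
                  sample(0:59, n_children, replace = TRUE), NA_integer_)
  # deaths must be observed before the interview
  death[!is.na(death) & (birth + death > interview_month)] <- NA_integer_
  children <- data.frame(woman_id = women$woman_id[wi], county_id = "C01",
                         birth_month = birth, death_age_months = death,
                         interview_month = interview_month,
                         stringsAsFactors = FALSE)
  new_cbh(women, children)
}

# brute-force exposure oracle: one explicit loop per child and age month,
# applying the documented allocation rules directly
oracle_exposure <- function(records, period_months = 24L) {
  ch <- records$children
  anchor <- max(ch$interview_month)
  seg_of <- function(m) {
    if (m == 0) 1L else if (m <= 11) 2L else if (m <= 23) 3L
    else if (m <= 35) 4L else if (m <= 47) 5L else 6L
  }
  n_per <- 0L
  rows <- list()
  for (i in seq_len(nrow(ch))) {
    dead <- !is.na(ch$death_age_months[i])
    last <- if (dead) ch$death_age_months[i] else
      min(59L, ch$interview_month[i] - ch$birth_month[i])
    for (m in 0:last) {
      cal <- ch$birth_month[i] + m
      p <- (anchor - cal) %/% period_months
      rows[[length(rows) + 1L]] <- c(seg_of(m), p,
                                     dead && m == ch$death_age_months[i])
    }
  }
  rows <- do.call(rbind, rows)
  n_per <- max(rows[, 2L]) + 1L
  D <- E <- matrix(0, 6L, n_per)
  for (r in seq_len(nrow(rows))) {
    E[rows[r, 1L], rows[r, 2L] + 1L] <- E[rows[r, 1L], rows[r, 2L] + 1L] + 1
    if (rows[r, 3L] == 1)
      D[rows[r, 1L], rows[r, 2L] + 1L] <- D[rows[r, 1L], rows[r, 2L] + 1L] + 1
  }
  list(D = D, E = E)
}

# brute-force SBH tally: independent per-woman loop
oracle_sbh <- function(records, grouping) {
  w <- records$women
  ch <- records$children
  out <- list()
  for (i in seq_len(nrow(w))) {
    kids <- ch[ch$woman_id == w$woman_id[i], , drop = FALSE]
    if (grouping == "MA") {
      age <- (w$interview_month[i] - w$birth_month[i]) %/% 12
      band <- (age - 15) %/% 5
      lab <- paste(15 + 5 * band, 19 + 5 * band, sep = "-")
    } else {
      if (nrow(kids) == 0) next
      tsfb <- (w$interview_month[i] - min(kids$birth_month)) %/% 12
      if (tsfb > 24) next
      band <- tsfb %/% 5
      lab <- paste(5 * band, 4 + 5 * band, sep = "-")
    }
    key <- paste(w$county_id[i], lab)
    if (is.null(out[[key]])) out[[key]] <- c(0, 0, 0)
    out[[key]] <- out[[key]] +
      c(1, nrow(kids), sum(!is.na(kids$death_age_months)))
  }
  out
}

# observations drawn exactly from the smoothing model, all five methods
model_sim_obs <- function(surface, graph, tau2, n_per_method = 120,
                          seed = 1, n_range = c(200, 5000)) {
  set.seed(seed)
  methods <- names(tau2)
  do.call(rbind, lapply(seq_along(methods), function(j) {
    d <- expand.grid(county_id = graph$nodes, year = surface$years,
                     stringsAsFactors = FALSE)
    d <- d[sample(nrow(d), min(n_per_method, nrow(d))), ]
    n <- sample(n_range[1]:n_range[2], nrow(d), replace = TRUE)
    lg <- logit(surface$Q[cbind(match(d$county_id, graph$nodes),
                                match(d$year, surface$years))]) +
      rnorm(nrow(d), 0, sqrt(tau2[j] / log(n)))
    data.frame(survey_id = "s1", method = methods[j], county_id = d$county_id,
               year = d$year, q5 = invlogit(lg), n = n,
               stringsAsFactors = FALSE)
  }))
}

TAU2_FIVE <- c(direct = 0.2, cohort_MA = 0.5, cohort_TFB = 0.5,
               period_MA = 0.4, period_TFB = 0.4)
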