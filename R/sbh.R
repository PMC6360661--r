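#' Aggregate complete birth histories to a summary birth-history table
#'
#' Collapses per-child microdata to the per-group totals a summary
#' birth-history (SBH) instrument records: women, children ever born (CEB)
#' and children dead (CD) at interview, grouped into 5-year bands of either
#' maternal age (15-19, ..., 45-49) or time since first birth (0-4, ...,
#' 20-24).
#'
#' Under the time-since-first-birth grouping, childless women and women
#' whose first birth lies more than 24 years back are excluded (with a
#' message); under maternal age every woman contributes.
#'
#' @param records a `u5m_cbh` (see [simulate_survey()] or [read_cbh_csv()]).
#' @param grouping `"maternal_age"` or `"time_since_first_birth"`.
#' @param by_county aggregate within county (default) or pool all records.
#' @return an `sbh_table`: data.frame with columns `county_id` (`"all"` when
#'   pooled), `group_label`, `women`, `ceb`, `cd`, and attributes `grouping`
#'   and `interview_year`.
#' @export
aggregate_sbh <- function(records,
                          grouping = c("maternal_age", "time_since_first_birth"),
                          by_county = TRUE) {
  stopifnot(inherits(records, "u5m_cbh"))
  grouping <- match.arg(grouping)
  w <- records$women
  if (nrow(w) == 0L) stop("no woman records to aggregate")
  ch <- records$children

  if (grouping == "maternal_age") {
    labels <- paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
    age_yr <- (w$interview_month - w$birth_month) %/% 12L
    grp <- labels[pmin(pmax((age_yr - 15L) %/% 5L + 1L, 1L), 7L)]
    keep <- rep(TRUE, nrow(w))
  } else {
    labels <- paste(seq(0, 20, 5), seq(4, 24, 5), sep = "-")
    first_birth <- tapply(ch$birth_month, ch$woman_id, min)
    fb <- first_birth[w$woman_id]
    tsfb <- (w$interview_month - fb) %/% 12L
    keep <- !is.na(tsfb) & tsfb <= 24L
    n_drop <- sum(!keep)
    if (n_drop > 0L)
      message("aggregate_sbh: excluded ", sum(is.na(tsfb)),
              " childless women and ", sum(!is.na(tsfb) & tsfb > 24L),
              " women with first birth > 24 years ago")
    grp <- rep(NA_character_, nrow(w))
    grp[keep] <- labels[tsfb[keep] %/% 5L + 1L]
  }

  cty <- if (by_county) w$county_id else rep("all", nrow(w))
  kept_ids <- w$woman_id[keep]
  ch_keep <- ch[ch$woman_id %in% kept_ids, , drop = FALSE]
  ch_grp <- grp[match(ch_keep$woman_id, w$woman_id)]
  ch_cty <- cty[match(ch_keep$woman_id, w$woman_id)]

  counties <- unique(cty[keep])
  out <- expand.grid(group_label = labels, county_id = counties,
                     stringsAsFactors = FALSE)[, 2:1]
  key <- function(c_, g_) paste(c_, g_, sep = "\r")
  wt <- table(key(cty[keep], grp[keep]))
  ct <- table(key(ch_cty, ch_grp))
  dt <- table(key(ch_cty[!is.na(ch_keep$death_age_months)],
                  ch_grp[!is.na(ch_keep$death_age_months)]))
  k <- key(out$county_id, out$group_label)
  out$women <- as.integer(ifelse(k %in% names(wt), wt[k], 0L))
  out$ceb <- as.integer(ifelse(k %in% names(ct), ct[k], 0L))
  out$cd <- as.integer(ifelse(k %in% names(dt), dt[k], 0L))
  stopifnot(all(out$cd <= out$ceb))
  structure(out, class = c("sbh_table", "data.frame"),
            grouping = if (grouping == "maternal_age") "MA" else "TFB",
            interview_year = year_of_month(records$interview_month))
}

#' @export
print.sbh_table <- function(x, ...) {
  cat("sbh_table (", attr(x, "grouping"), " grouping, interview ",
      attr(x, "interview_year"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
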