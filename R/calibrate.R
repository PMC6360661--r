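#' Coefficient containers for indirect estimation
#'
#' Cohort coefficients hold one row per 5-year group (`group_label`,
#' `beta0`...`beta4`, `u`, `ref_offset` in years before interview); period
#' coefficients one row per single year before the survey (`years_before`,
#' `beta0`, `beta1`, `u`); empirical distributions one row per group x year
#' (`group_label`, `years_before`, `birth_p`, `death_p`, each group's
#' columns summing to 1). Constructors validate and tag the grouping
#' (`"MA"` maternal age, `"TFB"` time since first birth) so tables cannot be
#' applied to mismatched SBH data.
#'
#' @param df data.frame with the documented columns.
#' @param grouping `"MA"` or `"TFB"`.
#' @return the classed data.frame.
#' @export
cohort_coefficients <- function(df, grouping) {
  need <- c("group_label", "beta0", "beta1", "beta2", "beta3", "beta4",
            "u", "ref_offset")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (is.unsorted(df$ref_offset)) stop("ref_offset must increase with group")
  if (any(df$ref_offset > 18)) stop("cohort reference offsets must be <= 18 years")
  structure(df[need], class = c("cohort_coefficients", "data.frame"),
            grouping = match.arg(grouping, c("MA", "TFB")))
}

#' @rdname cohort_coefficients
#' @export
period_coefficients <- function(df, grouping) {
  need <- c("years_before", "beta0", "beta1", "u")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$years_before > 24)) stop("period horizon is at most 25 years")
  structure(df[need], class = c("period_coefficients", "data.frame"),
            grouping = match.arg(grouping, c("MA", "TFB")))
}

#' @rdname cohort_coefficients
#' @export
empirical_distribution <- function(df, grouping) {
  need <- c("group_label", "years_before", "birth_p", "death_p")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$birth_p < 0) || any(df$death_p < 0))
    stop("distribution entries must be non-negative")
  structure(df[need], class = c("empirical_distribution", "data.frame"),
            grouping = match.arg(grouping, c("MA", "TFB")))
}

#' Build a synthetic calibration corpus
#'
#' Simulates a set of independent surveys spanning a wide range of true
#' mortality levels (and mildly varying fertility), each with complete birth
#' histories, to serve as training material for
#' [calibrate_coefficients()]. Each corpus entry uses a minimal 2-county
#' graph with a weak spatial field so the pooled records behave as one
#' population with a smooth time trend.
#'
#' @param n_surveys number of surveys (>= 20 recommended).
#' @param women women interviewed per survey (pooled over the 2 counties).
#' @param q5_range range of true under-five mortality levels spanned by the
#'   corpus (probability scale).
#' @param interview_year calendar year of every interview.
#' @param seed integer seed.
#' @return list of `u5m_cbh` objects.
#' @export
make_calibration_corpus <- function(n_surveys = 30, women = 8000,
                                    q5_range = c(0.03, 0.25),
                                    interview_year = 2010, seed = 42) {
  g <- make_lattice_adjacency(1, 2)
  alphas <- logit(seq(q5_range[1L], q5_range[2L], length.out = n_surveys))
  ## fertility varies across the corpus but must not be collinear with the
  ## mortality level, or the regression cannot separate the two signals
  fert_scale <- with_seed(sub_seed(seed, 0L),
                          sample(seq(0.85, 1.15, length.out = n_surveys)))
  base_fert <- eval(formals(sim_config)$fertility_rates)
  lapply(seq_len(n_surveys), function(i) {
    cfg <- sim_config(
      g, year_range = c(interview_year - 40L, interview_year),
      alpha = alphas[i], sigma2_S = 0.003, rho_s = 0.5, phi_t = 0.95,
      fertility_rates = pmin(base_fert * fert_scale[i], 0.95),
      surveys = list(survey_spec(interview_year, g$nodes,
                                 ceiling(women / 2),
                                 id = sprintf("cal%02d", i))),
      seed = sub_seed(seed, i))
    simulate_survey(cfg, sample_true_surface(cfg), 1L)
  })
}

## internal: exposure-weighted mean years before interview of the under-five
## child-months of each SBH group's children (the cohort reference offsets)
group_ref_offsets <- function(records, grouping) {
  w <- records$women
  ch <- records$children
  grp_w <- sbh_group_of(w, ch, grouping)
  g_ch <- grp_w[match(ch$woman_id, w$woman_id)]
  dead <- !is.na(ch$death_age_months)
  last <- ifelse(dead, ch$death_age_months,
                 pmin(59L, ch$interview_month - ch$birth_month))
  wt <- last + 1
  yrs_before <- (ch$interview_month - ch$birth_month - last / 2) / 12
  ok <- !is.na(g_ch)
  num <- tapply(wt[ok] * yrs_before[ok], g_ch[ok], sum)
  den <- tapply(wt[ok], g_ch[ok], sum)
  offs <- num / den
  offs[order(names(offs))]
}

## internal: the group label of each woman under a grouping scheme
sbh_group_of <- function(women, children, grouping) {
  if (grouping == "MA") {
    labels <- paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
    age_yr <- (women$interview_month - women$birth_month) %/% 12L
    labels[pmin(pmax((age_yr - 15L) %/% 5L + 1L, 1L), 7L)]
  } else {
    labels <- paste(seq(0, 20, 5), seq(4, 24, 5), sep = "-")
    fb <- tapply(children$birth_month, children$woman_id, min)[women$woman_id]
    tsfb <- (women$interview_month - fb) %/% 12L
    out <- rep(NA_character_, nrow(women))
    ok <- !is.na(tsfb) & tsfb <= 24L
    out[ok] <- labels[tsfb[ok] %/% 5L + 1L]
    out
  }
}

## internal: interpolator for logit(q5) over calendar time from a direct
## series; linear on the logit scale, flat beyond the observed range
direct_interpolator <- function(records) {
  est <- q5_direct(tabulate_exposure(records))
  est <- est[est$defined & est$q5 > 0 & est$q5 < 1, ]
  if (nrow(est) < 2L) stop("too few defined direct periods for calibration")
  function(year) stats::approx(est$year, logit(est$q5), xout = year,
                               rule = 2)$y
}

#' Calibrate indirect-method coefficients on a synthetic corpus
#'
#' Estimates, by ordinary least squares across corpus surveys, the
#' regression coefficients that convert summary birth-history proportions
#' into under-five mortality. The response for each cohort group is the
#' logit of the direct estimate (computed from the same simulated
#' population) interpolated at the group's reference time; the reference
#' offsets are the exposure-weighted mean years-before-interview of the
#' group's under-five child-months, capped at 18 years. Period coefficients
#' regress, separately for each year before the survey, the logit direct
#' estimate for that calendar year on the logit proportion dead among the
#' redistributed births of that year. Birth and death empirical
#' distributions are tallied from the corpus microdata (deaths indexed by
#' the dead child's year of birth). The offset U is fixed at 0: the corpus
#' represents a single synthetic region, so any regional level is absorbed
#' by the intercepts.
#'
#' @param corpus list of `u5m_cbh`, e.g. from [make_calibration_corpus()].
#' @param horizon period-method horizon in years before survey (max 25).
#' @param min_surveys minimum usable corpus surveys per regression.
#' @return a `u5m_coefficients` bundle: `cohort_MA`, `cohort_TFB`,
#'   `period_MA`, `period_TFB`, `dist_MA`, `dist_TFB`, plus a `diagnostics`
#'   data.frame of per-regression residual standard deviations.
#' @export
calibrate_coefficients <- function(corpus, horizon = 25L, min_surveys = 10L) {
  if (length(corpus) < 20L)
    warning("calibration corpus has fewer than 20 surveys")
  horizon <- min(as.integer(horizon), 25L)
  interp <- lapply(corpus, direct_interpolator)
  iy <- vapply(corpus, function(r) year_of_month(r$interview_month), 0L)

  diags <- list()
  bundle <- list()
  for (grouping in c("MA", "TFB")) {
    sbhs <- lapply(corpus, function(r)
      suppressMessages(aggregate_sbh(
        r, if (grouping == "MA") "maternal_age" else "time_since_first_birth",
        by_county = FALSE)))
    ratios <- lapply(corpus, function(r)
      parity_ratios(suppressMessages(aggregate_sbh(r, "maternal_age",
                                                   by_county = FALSE))))
    offs <- lapply(corpus, group_ref_offsets, grouping = grouping)

    ## ---- cohort regression, one fit per group ----
    labels <- sbhs[[1L]]$group_label
    rows <- list()
    for (g in labels) {
      dat <- do.call(rbind, lapply(seq_along(corpus), function(s) {
        tab <- sbhs[[s]]
        i <- match(g, tab$group_label)
        if (is.na(i) || tab$women[i] == 0 || tab$cd[i] == 0 ||
            tab$cd[i] >= tab$ceb[i]) return(NULL)
        r_i <- min(unname(offs[[s]][g]), 18)
        if (is.na(r_i)) return(NULL)
        data.frame(y = interp[[s]](iy[s] - r_i),
                   x1 = logit(tab$cd[i] / tab$ceb[i]),
                   x2 = tab$ceb[i] / tab$women[i],
                   x3 = ratios[[s]][[1L]], x4 = ratios[[s]][[2L]], r = r_i)
      }))
      if (is.null(dat) || nrow(dat) < min_surveys) next
      use_ratios <- grouping == "MA"
      xs <- if (use_ratios) c("x1", "x2", "x3", "x4") else c("x1", "x2")
      sds <- vapply(dat[xs], stats::sd, 0)
      if (any(sds < 1e-12))
        stop("calibration error: no variation in regressor ",
             xs[which(sds < 1e-12)[1L]], " for group ", g)
      fit <- stats::lm(stats::reformulate(xs, "y"), data = dat)
      b <- stats::coef(fit)
      rows[[g]] <- data.frame(
        group_label = g, beta0 = b[["(Intercept)"]], beta1 = b[["x1"]],
        beta2 = b[["x2"]],
        beta3 = if (use_ratios) b[["x3"]] else 0,
        beta4 = if (use_ratios) b[["x4"]] else 0,
        u = 0, ref_offset = mean(dat$r),
        n_surveys = nrow(dat), resid_sd = stats::sigma(fit))
    }
    ctab <- do.call(rbind, rows[order(vapply(rows, function(r) r$ref_offset, 0))])
    rownames(ctab) <- NULL
    diags[[paste0("cohort_", grouping)]] <-
      data.frame(regression = paste0("cohort_", grouping, "_", ctab$group_label),
                 n = ctab$n_surveys, resid_sd = ctab$resid_sd)
    bundle[[paste0("cohort_", grouping)]] <-
      cohort_coefficients(ctab, grouping)

    ## ---- empirical birth/death distributions, pooled over the corpus ----
    tal <- list()
    for (s in seq_along(corpus)) {
      r <- corpus[[s]]
      grp_w <- sbh_group_of(r$women, r$children, grouping)
      g_ch <- grp_w[match(r$children$woman_id, r$women$woman_id)]
      yb <- (r$children$interview_month - r$children$birth_month) %/% 12L
      ok <- !is.na(g_ch) & yb <= horizon - 1L
      dead <- ok & !is.na(r$children$death_age_months)
      tal[[s]] <- data.frame(g = c(g_ch[ok], g_ch[dead]),
                             t = c(yb[ok], yb[dead]),
                             what = rep(c("b", "d"), c(sum(ok), sum(dead))))
    }
    tal <- do.call(rbind, tal)
    dist <- expand.grid(group_label = sort(unique(tal$g)),
                        years_before = 0:(horizon - 1L),
                        stringsAsFactors = FALSE)
    bt <- table(tal$g[tal$what == "b"], tal$t[tal$what == "b"])
    dt <- table(tal$g[tal$what == "d"], tal$t[tal$what == "d"])
    lookup <- function(tab, g, t) {
      out <- numeric(length(g))
      i <- match(g, rownames(tab)); j <- match(as.character(t), colnames(tab))
      ok <- !is.na(i) & !is.na(j)
      out[ok] <- tab[cbind(i[ok], j[ok])]
      out
    }
    dist$birth_p <- lookup(bt, dist$group_label, dist$years_before)
    dist$death_p <- lookup(dt, dist$group_label, dist$years_before)
    for (g in unique(dist$group_label)) {
      i <- dist$group_label == g
      if (sum(dist$birth_p[i]) > 0)
        dist$birth_p[i] <- dist$birth_p[i] / sum(dist$birth_p[i])
      if (sum(dist$death_p[i]) > 0)
        dist$death_p[i] <- dist$death_p[i] / sum(dist$death_p[i])
    }
    keep <- vapply(unique(dist$group_label), function(g)
      sum(dist$birth_p[dist$group_label == g]) > 0 &&
        sum(dist$death_p[dist$group_label == g]) > 0, TRUE)
    dist <- dist[dist$group_label %in% names(keep)[keep], ]
    bundle[[paste0("dist_", grouping)]] <- empirical_distribution(dist, grouping)

    ## ---- period regression, one fit per year before survey ----
    prow <- list()
    pdat <- lapply(seq_along(corpus), function(s) {
      tab <- sbhs[[s]]
      tab2 <- tab
      attr(tab2, "grouping") <- grouping
      period_redistribute(tab2, bundle[[paste0("dist_", grouping)]])
    })
    for (t in 0:(horizon - 1L)) {
      dat <- do.call(rbind, lapply(seq_along(corpus), function(s) {
        py <- pdat[[s]]
        i <- match(t, py$years_before)
        if (is.na(i) || py$ceb[i] <= 0 || py$cd[i] <= 0 ||
            py$cd[i] >= py$ceb[i]) return(NULL)
        data.frame(y = interp[[s]](iy[s] - t),
                   x1 = logit(py$cd[i] / py$ceb[i]))
      }))
      if (is.null(dat) || nrow(dat) < min_surveys) next
      if (stats::sd(dat$x1) < 1e-12)
        stop("calibration error: no variation in regressor x1 at year ", t)
      fit <- stats::lm(y ~ x1, data = dat)
      b <- stats::coef(fit)
      prow[[as.character(t)]] <- data.frame(
        years_before = t, beta0 = b[[1L]], beta1 = b[[2L]], u = 0,
        n_surveys = nrow(dat), resid_sd = stats::sigma(fit))
    }
    ptab <- do.call(rbind, prow)
    rownames(ptab) <- NULL
    diags[[paste0("period_", grouping)]] <-
      data.frame(regression = paste0("period_", grouping, "_y", ptab$years_before),
                 n = ptab$n_surveys, resid_sd = ptab$resid_sd)
    bundle[[paste0("period_", grouping)]] <- period_coefficients(ptab, grouping)
  }
  bundle$diagnostics <- do.call(rbind, diags)
  rownames(bundle$diagnostics) <- NULL
  structure(bundle, class = "u5m_coefficients")
}

#' @export
print.u5m_coefficients <- function(x, ...) {
  cat("u5m_coefficients bundle:\n")
  for (nm in c("cohort_MA", "cohort_TFB"))
    cat(" ", nm, ":", nrow(x[[nm]]), "groups, ref offsets",
        sprintf("%.1f-%.1f yrs", min(x[[nm]]$ref_offset),
                max(x[[nm]]$ref_offset)), "\n")
  for (nm in c("period_MA", "period_TFB"))
    cat(" ", nm, ":", nrow(x[[nm]]), "years before survey\n")
  invisible(x)
}

#' Read and write coefficient bundles
#'
#' A bundle is stored as six CSV files in one directory:
#' `cohort_MA.csv`, `cohort_TFB.csv`, `period_MA.csv`, `period_TFB.csv`,
#' `dist_MA.csv`, `dist_TFB.csv`, using the documented column headers.
#'
#' @param bundle a `u5m_coefficients`.
#' @param dir directory path.
#' @return `read_coefficients()` returns a `u5m_coefficients`.
#' @export
write_coefficients <- function(bundle, dir) {
  stopifnot(inherits(bundle, "u5m_coefficients"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in c("MA", "TFB")) {
    utils::write.csv(bundle[[paste0("cohort_", g)]],
                     file.path(dir, paste0("cohort_", g, ".csv")),
                     row.names = FALSE)
    utils::write.csv(bundle[[paste0("period_", g)]],
                     file.path(dir, paste0("period_", g, ".csv")),
                     row.names = FALSE)
    utils::write.csv(bundle[[paste0("dist_", g)]],
                     file.path(dir, paste0("dist_", g, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  out <- list()
  for (g in c("MA", "TFB")) {
    out[[paste0("cohort_", g)]] <- cohort_coefficients(rd(paste0("cohort_", g, ".csv")), g)
    out[[paste0("period_", g)]] <- period_coefficients(rd(paste0("period_", g, ".csv")), g)
    out[[paste0("dist_", g)]] <- empirical_distribution(rd(paste0("dist_", g, ".csv")), g)
  }
  structure(out, class = "u5m_coefficients")
}

#' Packaged default coefficients
#'
#' Coefficients calibrated once, with [calibrate_coefficients()], on the
#' default synthetic corpus from [make_calibration_corpus()] (30 surveys of
#' 8000 women spanning true under-five mortality 30-250 per 1000, seed 42).
#' They are a documented synthetic stand-in for published coefficient sets,
#' which can be dropped in via [read_coefficients()].
#'
#' @return a `u5m_coefficients` bundle.
#' @export
default_coefficients <- function() {
  dir <- system.file("extdata", "synthetic_coefficients", package = "u5msmooth")
  if (dir == "") stop("packaged coefficient tables not found")
  read_coefficients(dir)
}
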