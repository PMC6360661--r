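#' Read and write birth-history and estimate CSV files
#'
#' All tabular interchange uses UTF-8 CSV with a header row. Complete birth
#' histories are stored one row per child (columns `woman_id`, `county_id`,
#' `woman_birth_month`, `interview_month`, `child_birth_month`,
#' `death_age_months` blank when alive), with childless women kept as a row
#' with blank child fields. SBH tables use columns `county_id`, `grouping`,
#' `group_label`, `interview_year`, `women`, `ceb`, `cd`. Estimates use
#' `survey_id`, `method`, `county_id`, `year`, `q5`, `n`.
#'
#' @param records a `u5m_cbh`.
#' @param path file path.
#' @return readers return the package container; writers return `path`
#'   invisibly.
#' @export
write_cbh_csv <- function(records, path) {
  stopifnot(inherits(records, "u5m_cbh"))
  w <- records$women
  ch <- records$children
  childless <- !w$woman_id %in% ch$woman_id
  rows <- rbind(
    data.frame(woman_id = ch$woman_id, county_id = ch$county_id,
               woman_birth_month = w$birth_month[match(ch$woman_id, w$woman_id)],
               interview_month = ch$interview_month,
               child_birth_month = ch$birth_month,
               death_age_months = ch$death_age_months),
    data.frame(woman_id = w$woman_id[childless],
               county_id = w$county_id[childless],
               woman_birth_month = w$birth_month[childless],
               interview_month = w$interview_month[childless],
               child_birth_month = NA_integer_,
               death_age_months = NA_integer_))
  rows <- rows[order(rows$woman_id, rows$child_birth_month), ]
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cbh_csv
#' @param survey_id label attached to the loaded records.
#' @export
read_cbh_csv <- function(path, survey_id = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("woman_id", "county_id", "woman_birth_month", "interview_month",
            "child_birth_month", "death_age_months")
  if (!all(need %in% names(d)))
    stop("CBH file ", path, " missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  wrows <- !duplicated(d$woman_id)
  women <- data.frame(woman_id = d$woman_id[wrows],
                      county_id = d$county_id[wrows],
                      birth_month = as.integer(d$woman_birth_month[wrows]),
                      interview_month = as.integer(d$interview_month[wrows]),
                      stringsAsFactors = FALSE)
  has_child <- !is.na(d$child_birth_month)
  children <- data.frame(woman_id = d$woman_id[has_child],
                         county_id = d$county_id[has_child],
                         birth_month = as.integer(d$child_birth_month[has_child]),
                         death_age_months = as.integer(d$death_age_months[has_child]),
                         interview_month = as.integer(d$interview_month[has_child]),
                         stringsAsFactors = FALSE)
  structure(list(women = women, children = children,
                 survey_id = survey_id %||% basename(path),
                 interview_month = max(women$interview_month)),
            class = "u5m_cbh")
}

#' @rdname write_cbh_csv
#' @param sbh an `sbh_table`.
#' @export
write_sbh_csv <- function(sbh, path) {
  stopifnot(inherits(sbh, "sbh_table"))
  out <- data.frame(county_id = sbh$county_id, grouping = attr(sbh, "grouping"),
                    group_label = sbh$group_label,
                    interview_year = attr(sbh, "interview_year"),
                    women = sbh$women, ceb = sbh$ceb, cd = sbh$cd)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cbh_csv
#' @export
read_sbh_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county_id", "grouping", "group_label", "interview_year",
            "women", "ceb", "cd")
  if (!all(need %in% names(d)))
    stop("SBH file ", path, " missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (length(unique(d$grouping)) != 1L)
    stop("SBH file must hold a single grouping")
  if (any(d$cd > d$ceb)) stop("children dead exceed children ever born")
  structure(d[, c("county_id", "group_label", "women", "ceb", "cd")],
            class = c("sbh_table", "data.frame"),
            grouping = d$grouping[1L], interview_year = d$interview_year[1L])
}

#' @rdname write_cbh_csv
#' @param estimates estimates data.frame.
#' @export
write_estimates_csv <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cbh_csv
#' @export
read_estimates_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("survey_id", "method", "county_id", "year", "q5", "n")
  if (!all(need %in% names(d)))
    stop("estimates file ", path, " missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Validate pipeline input files against their schemas
#'
#' Checks every supplied file and returns one row per violation with the
#' file, the offending data row number and a message; an empty data.frame
#' means every check passed. Checked rules: estimates `q5` strictly in
#' (0, 1) and `n >= 3`; SBH `cd <= ceb` and `women >= 0`; CBH
#' `death_age_months` in 0-59 and child birth month not after the
#' interview; the adjacency file must parse into a graph.
#'
#' @param paths named list with any of `estimates`, `sbh`, `cbh`, `graph`.
#' @return data.frame with columns `file`, `row`, `message`.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  note <- function(file, row, msg)
    v[[length(v) + 1L]] <<- data.frame(file = file, row = row, message = msg,
                                       stringsAsFactors = FALSE)
  read_or_note <- function(path) {
    tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
             error = function(e) {
               note(path, NA_integer_, paste("parse error:", conditionMessage(e)))
               NULL
             })
  }
  if (!is.null(paths$estimates)) {
    d <- read_or_note(paths$estimates)
    if (!is.null(d)) {
      for (i in which(!(d$q5 > 0 & d$q5 < 1)))
        note(paths$estimates, i, "q5 outside (0, 1)")
      for (i in which(d$n < 3))
        note(paths$estimates, i, "sample size n below 3")
    }
  }
  if (!is.null(paths$sbh)) {
    d <- read_or_note(paths$sbh)
    if (!is.null(d)) {
      for (i in which(d$cd > d$ceb))
        note(paths$sbh, i, "children dead exceed children ever born")
      for (i in which(d$women < 0))
        note(paths$sbh, i, "negative woman count")
    }
  }
  if (!is.null(paths$cbh)) {
    d <- read_or_note(paths$cbh)
    if (!is.null(d)) {
      bad_age <- which(!is.na(d$death_age_months) &
                         (d$death_age_months < 0 | d$death_age_months > 59))
      for (i in bad_age) note(paths$cbh, i, "death_age_months outside 0-59")
      late <- which(!is.na(d$child_birth_month) &
                      d$child_birth_month > d$interview_month)
      for (i in late) note(paths$cbh, i, "child born after interview")
    }
  }
  if (!is.null(paths$graph)) {
    tryCatch(read_adjacency(paths$graph),
             error = function(e) note(paths$graph, NA_integer_,
                                      paste("graph error:", conditionMessage(e))),
             warning = function(w) note(paths$graph, NA_integer_,
                                        paste("graph warning:", conditionMessage(w))))
  }
  if (!length(v))
    return(data.frame(file = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full estimation pipeline
#'
#' Chains simulate -> estimate (direct + four indirect methods) -> fit ->
#' assess, writing every intermediate artifact plus a manifest (stage, file,
#' md5 hash, seed, duration) to `out_dir`, so a rerun with the same
#' configuration is bit-reproducible.
#'
#' @param config a [sim_config()] describing the study setting.
#' @param out_dir output directory (created if needed).
#' @param mcmc an [mcmc_control()].
#' @param priors a [smoother_priors()].
#' @param coeffs indirect-method coefficients; defaults to the packaged
#'   synthetic calibration.
#' @param holdout_fraction if positive, additionally runs
#'   [cross_validate()] with this fraction.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `surface`, `estimates`, `fit`,
#'   `assessment`, `inequality`, `crossval` (NULL unless requested) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, mcmc = mcmc_control(),
                         priors = smoother_priors(),
                         coeffs = default_coefficients(),
                         holdout_fraction = 0, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$surveys)) stop("config defines no surveys")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  stamp <- function(stage, files, t0) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), seed = config$seed,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      stringsAsFactors = FALSE)
  }

  ## stage 1: simulate
  t0 <- Sys.time()
  sim <- simulate_all_surveys(config)
  gpath <- file.path(out_dir, "adjacency.txt")
  write_adjacency(config$graph, gpath)
  files <- gpath
  for (i in seq_along(sim$surveys)) {
    sv <- config$surveys[[i]]
    if (sv$collects_cbh) {
      p <- file.path(out_dir, paste0("cbh_", sv$id, ".csv"))
      write_cbh_csv(sim$surveys[[i]], p)
      files <- c(files, p)
    }
    if (sv$collects_sbh) {
      for (grp in c("maternal_age", "time_since_first_birth")) {
        tab <- suppressMessages(aggregate_sbh(sim$surveys[[i]], grp))
        p <- file.path(out_dir, paste0("sbh_", sv$id, "_",
                                       attr(tab, "grouping"), ".csv"))
        write_sbh_csv(tab, p)
        files <- c(files, p)
      }
    }
  }
  stamp("simulate", files, t0)
  if (!quiet) message("simulated ", length(sim$surveys), " survey(s)")

  ## stage 2: estimate
  t0 <- Sys.time()
  est <- list()
  for (i in seq_along(sim$surveys)) {
    sv <- config$surveys[[i]]
    rec <- sim$surveys[[i]]
    if (sv$collects_cbh)
      est[[length(est) + 1L]] <- estimate_direct(rec)
    if (sv$collects_sbh) {
      for (grp in c("maternal_age", "time_since_first_birth")) {
        tab <- suppressMessages(aggregate_sbh(rec, grp))
        est[[length(est) + 1L]] <- estimate_indirect(tab, coeffs,
                                                     survey_id = sv$id)
      }
    }
  }
  estimates <- do.call(rbind, est)
  if (is.null(estimates) || nrow(estimates) == 0L)
    stop("pipeline halted at stage 'estimate': no usable estimates")
  epath <- file.path(out_dir, "estimates.csv")
  write_estimates_csv(estimates, epath)
  stamp("estimate", epath, t0)
  if (!quiet) message(nrow(estimates), " estimates from ",
                      length(unique(estimates$method)), " method(s)")

  ## stage 3: fit
  t0 <- Sys.time()
  years <- seq.int(min(c(estimates$year, config$year_range[1L])),
                   max(c(estimates$year, config$year_range[2L])))
  fit <- u5m_smooth(estimates, config$graph, years = years, mcmc = mcmc,
                    priors = priors, quiet = quiet)
  spath <- file.path(out_dir, "posterior_summary.csv")
  utils::write.csv(fit$summaries, spath, row.names = FALSE)
  stamp("fit", spath, t0)

  ## stage 3b: optional cross-validation
  cv <- NULL
  if (holdout_fraction > 0) {
    t0 <- Sys.time()
    cv <- suppressWarnings(cross_validate(
      estimates, config$graph, mcmc = mcmc, priors = priors,
      holdout_fraction = holdout_fraction, seed = config$seed, years = years))
    cvpath <- file.path(out_dir, "crossval.csv")
    utils::write.csv(data.frame(rmse = cv$rmse, bias = cv$bias,
                                n_test = cv$n_test), cvpath, row.names = FALSE)
    stamp("crossval", cvpath, t0)
  }

  ## stage 4: assess (only if the surface covers the goal years)
  t0 <- Sys.time()
  assessment <- inequality <- NULL
  if (all(c(1990, 2000, 2013) %in% years)) {
    res <- assess_surface(fit$summaries)
    assessment <- res$assessment
    inequality <- res$inequality
    apath <- file.path(out_dir, "assessment.csv")
    ipath <- file.path(out_dir, "inequality.csv")
    utils::write.csv(assessment, apath, row.names = FALSE)
    utils::write.csv(inequality, ipath, row.names = FALSE)
    stamp("assess", c(apath, ipath), t0)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(surface = sim$surface, estimates = estimates, fit = fit,
                 assessment = assessment, inequality = inequality,
                 crossval = cv, manifest = manifest))
}
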