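#' Hold-out cross-validation of the smoother
#'
#' Randomly holds out a fraction of observations within every
#' survey x method stratum, refits the model on the remainder, and predicts
#' the held-out under-five mortality on the probability scale from the
#' posterior mean surface. Strata with fewer than `min_stratum`
#' observations contribute no hold-outs (with a warning).
#'
#' @param obs observation data.frame (see [u5m_smooth()]).
#' @param graph a [u5m_graph].
#' @param mcmc an [mcmc_control()].
#' @param priors a [smoother_priors()].
#' @param holdout_fraction fraction held out per stratum (default 0.10;
#'   must be > 0).
#' @param seed seed for the hold-out draw.
#' @param years prediction years passed to [u5m_smooth()]; defaults to the
#'   range of all observations so held-out years stay predictable.
#' @param min_stratum minimum stratum size eligible for hold-out.
#' @param ... further arguments to [u5m_smooth()].
#' @return list with `rmse`, `bias` (probability scale), `n_test`,
#'   `predictions` (data.frame of held-out rows with `pred`), and the
#'   refitted model `fit`.
#' @export
cross_validate <- function(obs, graph, mcmc = mcmc_control(),
                           priors = smoother_priors(),
                           holdout_fraction = 0.10, seed = 1L, years = NULL,
                           min_stratum = 10L, ...) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must lie in (0, 1)")
  obs <- prepare_observations(obs, graph)
  if (is.null(years)) years <- seq.int(min(obs$year), max(obs$year))
  strat <- interaction(obs$survey_id, obs$method, drop = TRUE)
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(strat), function(s) {
      rows <- which(strat == s)
      if (length(rows) < min_stratum) {
        warning("stratum ", s, " has fewer than ", min_stratum,
                " observations; skipped", call. = FALSE)
        return(integer())
      }
      sample(rows, max(1L, round(holdout_fraction * length(rows))))
    }))
  })
  if (length(test_idx) == 0L) stop("empty hold-out test set")
  train <- obs[-test_idx, , drop = FALSE]
  test <- obs[test_idx, , drop = FALSE]
  fit <- u5m_smooth(train, graph, years = years, mcmc = mcmc,
                    priors = priors, ...)
  mn <- apply(fit$samples, c(2, 3), mean)
  cellt <- match(test$county_id, fit$counties) +
    (match(test$year, fit$years) - 1L) * length(fit$counties)
  test$pred <- as.vector(mn)[cellt]
  err <- test$pred - test$q5
  list(rmse = sqrt(mean(err^2)), bias = mean(err), n_test = nrow(test),
       predictions = test, fit = fit)
}
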