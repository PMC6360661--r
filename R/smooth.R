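#' Observation-level noise variance
#'
#' Each estimate entering the smoother carries Gaussian noise on the logit
#' scale whose variance combines a method-specific factor `tau2` with the
#' log of the contributing sample size, so that information grows with the
#' log of n and a census can never swamp the surveys. The default reading
#' divides by log(n) (weight proportional to log n); the alternative
#' multiplicative reading is available via `model = "multiply"`.
#'
#' @param n sample size (women contributing); must be >= 3 so log(n) > 1.
#' @param tau2 positive method-specific variance factor.
#' @param model `"divide"` (default) or `"multiply"`.
#' @return positive numeric vector of variances.
#' @export
observation_variance <- function(n, tau2, model = c("divide", "multiply")) {
  model <- match.arg(model)
  if (any(n < 3)) stop("sample size must be at least 3")
  if (any(tau2 <= 0)) stop("tau2 must be positive")
  if (model == "divide") tau2 / log(n) else tau2 * log(n)
}

#' MCMC settings
#'
#' @param iterations total MCMC iterations.
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed for the sampler.
#' @return an `mcmc_control` list; the retained sample count is
#'   `(iterations - burn_in) / thin`.
#' @export
mcmc_control <- function(iterations = 110000L, burn_in = 10000L, thin = 10L,
                         seed = 1L) {
  stopifnot(is_count(iterations), is_count(burn_in, min = 0), is_count(thin))
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  n_keep <- (iterations - burn_in) %/% thin
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_keep = as.integer(n_keep), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Priors and fixed values for the smoother
#'
#' Weakly informative defaults: alpha ~ Normal(0, 10^2); the process and
#' method standard deviations ~ half-Normal(0, 5^2); rho_s ~ Uniform(0, 1);
#' phi_t ~ Uniform(-1, 1). Any parameter can be pinned through `fixed`
#' (e.g. `fixed = list(rho_s = 0.9, tau2 = c(direct = 0.2))`), which is how
#' closed-form oracle checks condition on known hyper-parameters.
#'
#' @param alpha_mean,alpha_sd Gaussian prior for the intercept.
#' @param sd_S_scale half-Normal scale for the process SD.
#' @param tau_scale half-Normal scale for the method noise SDs.
#' @param fixed named list of pinned parameters among `alpha`, `sigma2_S`,
#'   `rho_s`, `phi_t`, `tau2`.
#' @return a `u5m_priors` list.
#' @export
smoother_priors <- function(alpha_mean = 0, alpha_sd = 10, sd_S_scale = 5,
                            tau_scale = 5, fixed = list()) {
  ok <- c("alpha", "sigma2_S", "rho_s", "phi_t", "tau2")
  if (length(setdiff(names(fixed), ok)))
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), ok), collapse = ", "))
  structure(list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 sd_S_scale = sd_S_scale, tau_scale = tau_scale,
                 fixed = fixed),
            class = "u5m_priors")
}

## internal: validate/clean the observation table
prepare_observations <- function(obs, graph) {
  need <- c("survey_id", "method", "county_id", "year", "q5", "n")
  if (!all(need %in% names(obs)))
    stop("observations must have columns ",
         paste(need, collapse = ", "))
  if (any(!obs$county_id %in% graph$nodes))
    stop("observation references unknown county: ",
         paste(utils::head(setdiff(obs$county_id, graph$nodes)), collapse = ", "))
  if (any(obs$q5 <= 0 | obs$q5 >= 1))
    stop("q5 must lie strictly in (0, 1)")
  small <- obs$n < 3
  if (any(small)) {
    warning("rejecting ", sum(small), " observation(s) with n < 3")
    obs <- obs[!small, , drop = FALSE]
  }
  if (nrow(obs) == 0L) stop("no usable observations")
  obs
}

#' Fit the Bayesian spatio-temporal smoothing model
#'
#' Fuses every per-survey, per-method county-year under-five mortality
#' estimate into a single posterior surface. The model is
#' \deqn{logit(Q_{ijkt}) = \alpha + S_{kt} + Z_{ijkt},}
#' with S a separable CAR (space) x AR(1) (time) Gaussian field (see
#' [build_precision()]) and Z heteroscedastic Gaussian noise with variance
#' `tau2_j / log(n)` (see [observation_variance()]). Inference is a bespoke
#' MCMC: the Gaussian field and the intercept are updated by conjugate Gibbs
#' steps, the hyper-parameters (process variance, spatial and temporal
#' dependence, method noise factors) by adaptive random-walk Metropolis
#' whose proposal scales target 20-40% acceptance during burn-in and are
#' frozen afterwards. County-years with no data are predicted from the
#' process prior conditioned on their neighbours (no noise term).
#'
#' @param obs data.frame of observations: `survey_id`, `method`,
#'   `county_id`, `year`, `q5` in (0,1), `n` (>= 3; smaller records are
#'   rejected with a warning).
#' @param graph a [u5m_graph]; a disconnected graph triggers a warning and
#'   is fitted as independent blocks of the CAR precision.
#' @param years calendar years to predict (default: the observed range);
#'   may extend beyond the data.
#' @param mcmc an [mcmc_control()].
#' @param priors a [smoother_priors()].
#' @param variance_model how log(n) enters the noise variance; see
#'   [observation_variance()].
#' @param quiet suppress progress messages.
#' @return an object of class `u5m_smooth` with retained posterior samples
#'   of the mortality surface (`samples`: n_keep x K x T array on the
#'   probability scale), hyper-parameter `traces`, Metropolis
#'   `acceptance` rates, and the training data. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`,
#'   `plot`.
#' @export
u5m_smooth <- function(obs, graph, years = NULL, mcmc = mcmc_control(),
                       priors = smoother_priors(),
                       variance_model = c("divide", "multiply"),
                       quiet = TRUE) {
  stopifnot(inherits(graph, "u5m_graph"), inherits(mcmc, "mcmc_control"),
            inherits(priors, "u5m_priors"))
  variance_model <- match.arg(variance_model)
  obs <- prepare_observations(obs, graph)
  cl <- match.call()

  counties <- graph$nodes
  K <- length(counties)
  if (is.null(years)) years <- seq.int(min(obs$year), max(obs$year))
  Tn <- length(years)
  if (any(!obs$year %in% years)) stop("observation year outside `years`")
  KT <- K * Tn
  cell <- match(obs$county_id, counties) + (match(obs$year, years) - 1L) * K
  y <- logit(obs$q5)
  logn <- log(obs$n)
  methods <- sort(unique(obs$method))
  m_idx <- match(obs$method, methods)
  J <- length(methods)

  fx <- priors$fixed
  Qs_of <- function(rho) car_precision(graph, rho)
  Qt_of <- function(phi) ar1_precision(Tn, phi)
  quad_S <- function(Smat, Qs, Qt) sum((Qs %*% Smat) * (Smat %*% Qt))

  ## observation weights (precision contributions) given tau2 by method
  w_of <- function(tau2) {
    v <- observation_variance(obs$n, tau2[m_idx], variance_model)
    1 / v
  }

  ## initial state
  alpha <- if (!is.null(fx$alpha)) fx$alpha else mean(y)
  sigma2 <- if (!is.null(fx$sigma2_S)) fx$sigma2_S else stats::var(y) / 2 + 0.01
  rho <- if (!is.null(fx$rho_s)) fx$rho_s else 0.5
  phi <- if (!is.null(fx$phi_t)) fx$phi_t else 0.5
  tau2 <- stats::setNames(rep(0.5, J), methods)
  if (!is.null(fx$tau2)) {
    if (is.null(names(fx$tau2)) && length(fx$tau2) == 1L)
      fx$tau2 <- stats::setNames(rep(fx$tau2, J), methods)
    tau2[names(fx$tau2)] <- fx$tau2
  }
  fixed_tau <- if (!is.null(fx$tau2)) names(fx$tau2) else character()
  Smat <- matrix(0, K, Tn)
  Qs <- Qs_of(rho); Qt <- Qt_of(phi)
  ldQs <- as.numeric(determinant(Qs)$modulus)
  ldQt <- as.numeric(determinant(Qt)$modulus)

  ## half-normal log prior on an SD
  lp_hn <- function(s, scale) -0.5 * (s / scale)^2
  ## adaptive proposal bookkeeping: log sd_S, transformed rho, phi, log tau
  pnames <- c("sigma2_S", "rho_s", "phi_t", paste0("tau2_", methods))
  scales <- stats::setNames(rep(0.3, 3L + J), pnames)
  acc <- stats::setNames(numeric(3L + J), pnames)
  acc_batch <- stats::setNames(numeric(3L + J), pnames)
  batch_n <- 0L

  n_keep <- mcmc$n_keep
  S_keep <- matrix(NA_real_, n_keep, KT)
  trace <- matrix(NA_real_, n_keep, 4L + J,
                  dimnames = list(NULL, c("alpha", "sigma2_S", "rho_s",
                                          "phi_t", paste0("tau2_", methods))))
  keep_i <- 0L

  with_seed(mcmc$seed, {
    for (it in seq_len(mcmc$iterations)) {
      w <- w_of(tau2)
      ## --- Gibbs: latent field S ---
      wc <- numeric(KT); bc <- numeric(KT)
      agg_w <- rowsum(w, cell); agg_b <- rowsum(w * (y - alpha), cell)
      ii <- as.integer(rownames(agg_w))
      wc[ii] <- agg_w; bc[ii] <- agg_b
      P <- kronecker(Qt, Qs) / sigma2
      diag(P) <- diag(P) + wc
      R <- chol(P)
      mu <- backsolve(R, backsolve(R, bc, transpose = TRUE))
      Svec <- mu + backsolve(R, stats::rnorm(KT))
      Smat <- matrix(Svec, K, Tn)
      if (!all(is.finite(Svec)))
        stop("non-finite field update; parameters: alpha=", alpha,
             " sigma2_S=", sigma2, " rho_s=", rho, " phi_t=", phi)

      ## --- Gibbs: intercept ---
      if (is.null(fx$alpha)) {
        r0 <- y - Svec[cell]
        prec <- sum(w) + 1 / priors$alpha_sd^2
        mn <- (sum(w * r0) + priors$alpha_mean / priors$alpha_sd^2) / prec
        alpha <- stats::rnorm(1L, mn, sqrt(1 / prec))
      }

      ## --- MH: process variance (on log-SD scale) ---
      if (is.null(fx$sigma2_S)) {
        q_cur <- quad_S(Smat, Qs, Qt)
        ls <- 0.5 * log(sigma2)
        ls_p <- ls + stats::rnorm(1L, 0, scales["sigma2_S"])
        s2_p <- exp(2 * ls_p)
        lr <- (-KT * ls_p - q_cur / (2 * s2_p) + lp_hn(exp(ls_p), priors$sd_S_scale) + ls_p) -
              (-KT * ls   - q_cur / (2 * sigma2) + lp_hn(exp(ls),  priors$sd_S_scale) + ls)
        if (log(stats::runif(1L)) < lr) {
          sigma2 <- s2_p
          acc_batch["sigma2_S"] <- acc_batch["sigma2_S"] + 1
          acc["sigma2_S"] <- acc["sigma2_S"] + 1
        }
      }

      ## --- MH: spatial dependence rho_s in [0, 1) ---
      if (is.null(fx$rho_s) && K > 1L) {
        tr <- stats::qlogis(max(min(rho, 1 - 1e-9), 1e-9))
        tr_p <- tr + stats::rnorm(1L, 0, scales["rho_s"])
        rho_p <- stats::plogis(tr_p)
        Qs_p <- Qs_of(rho_p)
        ld_p <- as.numeric(determinant(Qs_p)$modulus)
        lr <- (Tn / 2 * ld_p - quad_S(Smat, Qs_p, Qt) / (2 * sigma2) +
                 log(rho_p) + log(1 - rho_p)) -
              (Tn / 2 * ldQs - quad_S(Smat, Qs, Qt) / (2 * sigma2) +
                 log(rho) + log(1 - rho))
        if (is.finite(lr) && log(stats::runif(1L)) < lr) {
          rho <- rho_p; Qs <- Qs_p; ldQs <- ld_p
          acc_batch["rho_s"] <- acc_batch["rho_s"] + 1
          acc["rho_s"] <- acc["rho_s"] + 1
        }
      }

      ## --- MH: temporal dependence phi_t in (-1, 1) ---
      if (is.null(fx$phi_t) && Tn > 1L) {
        tr <- atanh(max(min(phi, 1 - 1e-9), -1 + 1e-9))
        tr_p <- tr + stats::rnorm(1L, 0, scales["phi_t"])
        phi_p <- tanh(tr_p)
        Qt_p <- Qt_of(phi_p)
        ld_p <- as.numeric(determinant(Qt_p)$modulus)
        lr <- (K / 2 * ld_p - quad_S(Smat, Qs, Qt_p) / (2 * sigma2) +
                 log1p(-phi_p^2)) -
              (K / 2 * ldQt - quad_S(Smat, Qs, Qt) / (2 * sigma2) +
                 log1p(-phi^2))
        if (is.finite(lr) && log(stats::runif(1L)) < lr) {
          phi <- phi_p; Qt <- Qt_p; ldQt <- ld_p
          acc_batch["phi_t"] <- acc_batch["phi_t"] + 1
          acc["phi_t"] <- acc["phi_t"] + 1
        }
      }

      ## --- MH: method noise factors (on log-SD scale) ---
      resid <- y - alpha - Svec[cell]
      for (j in seq_len(J)) {
        if (methods[j] %in% fixed_tau) next
        pj <- paste0("tau2_", methods[j])
        sel <- m_idx == j
        nj <- sum(sel)
        if (nj == 0L) next
        ssq <- if (variance_model == "divide")
          sum(logn[sel] * resid[sel]^2) else sum(resid[sel]^2 / logn[sel])
        lt <- 0.5 * log(tau2[j])
        lt_p <- lt + stats::rnorm(1L, 0, scales[pj])
        t2_p <- exp(2 * lt_p)
        lr <- (-nj * lt_p - ssq / (2 * t2_p) + lp_hn(exp(lt_p), priors$tau_scale) + lt_p) -
              (-nj * lt   - ssq / (2 * tau2[j]) + lp_hn(exp(lt), priors$tau_scale) + lt)
        if (log(stats::runif(1L)) < lr) {
          tau2[j] <- t2_p
          acc_batch[pj] <- acc_batch[pj] + 1
          acc[pj] <- acc[pj] + 1
        }
      }

      ## --- adapt proposal scales during burn-in only ---
      batch_n <- batch_n + 1L
      if (it <= mcmc$burn_in && batch_n == 50L) {
        rate <- acc_batch / batch_n
        scales <- scales * exp(pmin(pmax(rate - 0.3, -0.25), 0.25))
        acc_batch[] <- 0; batch_n <- 0L
      } else if (batch_n == 50L) {
        acc_batch[] <- 0; batch_n <- 0L
      }

      ## --- retain ---
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        S_keep[keep_i, ] <- alpha + Svec
        trace[keep_i, ] <- c(alpha, sigma2, rho, phi, tau2)
      }
      if (!quiet && it %% 5000L == 0L)
        message("iteration ", it, " / ", mcmc$iterations)
    }
  })

  samples <- array(invlogit(S_keep), dim = c(n_keep, K, Tn),
                   dimnames = list(NULL, counties, years))
  fit <- structure(list(samples = samples, traces = trace,
                        acceptance = acc / mcmc$iterations,
                        obs = obs, cell = cell, graph = graph,
                        counties = counties, years = years,
                        methods = methods, variance_model = variance_model,
                        mcmc = mcmc, priors = priors, call = cl),
                   class = "u5m_smooth")
  fit$summaries <- summarize_posterior(samples)
  fit
}

#' Summarise a posterior mortality surface
#'
#' Posterior mean and equal-tailed 95% credible interval per county-year,
#' reported as deaths per 1000 live births.
#'
#' @param samples n_samples x K x T array of mortality probabilities with
#'   county and year dimnames (at least 100 samples).
#' @return data.frame: `county_id`, `year`, `mean`, `lo95`, `hi95` (per
#'   1000).
#' @export
summarize_posterior <- function(samples) {
  stopifnot(length(dim(samples)) == 3L)
  if (dim(samples)[1L] < 100L) stop("need at least 100 retained samples")
  mn <- apply(samples, c(2, 3), mean)
  lo <- apply(samples, c(2, 3), stats::quantile, probs = 0.025)
  hi <- apply(samples, c(2, 3), stats::quantile, probs = 0.975)
  out <- expand.grid(county_id = dimnames(samples)[[2L]],
                     year = as.integer(dimnames(samples)[[3L]]),
                     stringsAsFactors = FALSE)
  out$mean <- 1000 * as.vector(mn)
  out$lo95 <- 1000 * as.vector(lo)
  out$hi95 <- 1000 * as.vector(hi)
  out
}

#' @export
print.u5m_smooth <- function(x, ...) {
  cat("Bayesian spatio-temporal U5M smoother\n")
  cat("  counties:", length(x$counties), " years:", min(x$years), "-",
      max(x$years), "\n")
  cat("  observations:", nrow(x$obs), "from", length(unique(x$obs$survey_id)),
      "survey(s),", length(x$methods), "method(s)\n")
  cat("  retained samples:", dim(x$samples)[1L], "\n")
  cat("  posterior hyper-parameter means:\n")
  print(round(colMeans(x$traces), 4))
  invisible(x)
}

#' @export
summary.u5m_smooth <- function(object, ...) object$summaries

#' @export
coef.u5m_smooth <- function(object, ...) colMeans(object$traces)

#' @export
predict.u5m_smooth <- function(object, counties = NULL, years = NULL, ...) {
  s <- object$summaries
  if (!is.null(counties)) s <- s[s$county_id %in% counties, , drop = FALSE]
  if (!is.null(years)) s <- s[s$year %in% years, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' @export
fitted.u5m_smooth <- function(object, ...) {
  mn <- apply(object$samples, c(2, 3), mean)
  as.vector(mn)[object$cell]
}

#' @export
residuals.u5m_smooth <- function(object, ...) {
  ## logit-scale residuals of the training observations around the
  ## posterior mean field
  lg <- apply(logit(object$samples), c(2, 3), mean)
  logit(object$obs$q5) - as.vector(lg)[object$cell]
}

#' @export
simulate.u5m_smooth <- function(object, nsim = 1, seed = NULL, ...) {
  idx <- with_seed(seed, sample.int(dim(object$samples)[1L], nsim,
                                    replace = TRUE))
  object$samples[idx, , , drop = FALSE]
}

#' @export
plot.u5m_smooth <- function(x, counties = NULL, per_1000 = TRUE, ...) {
  s <- x$summaries
  if (is.null(counties)) counties <- utils::head(x$counties, 6L)
  sc <- if (per_1000) 1 else 1 / 1000
  ylim <- range(s$lo95[s$county_id %in% counties],
                s$hi95[s$county_id %in% counties]) * sc
  graphics::plot(NA, xlim = range(x$years), ylim = ylim, xlab = "year",
                 ylab = if (per_1000) "U5M per 1000 live births" else "U5M",
                 ...)
  cols <- grDevices::hcl.colors(length(counties), "Dark 3")
  for (i in seq_along(counties)) {
    si <- s[s$county_id == counties[i], ]
    graphics::polygon(c(si$year, rev(si$year)),
                      c(si$lo95, rev(si$hi95)) * sc,
                      col = grDevices::adjustcolor(cols[i], 0.15), border = NA)
    graphics::lines(si$year, si$mean * sc, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = counties, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
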