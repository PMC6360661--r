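test_that("observation variance follows tau2 / log(n)", {
  expect_equal(observation_variance(exp(3), 1), 1 / 3)
  expect_equal(observation_variance(exp(3), 2), 2 / 3)      # doubles with tau2
  expect_lt(observation_variance(10000, 1), observation_variance(100, 1))
  expect_equal(observation_variance(exp(2), 1, model = "multiply"), 2)
  expect_error(observation_variance(2, 1), "at least 3")
  expect_error(observation_variance(10, 0), "positive")
})

fixed_priors <- function(tau2, alpha = 0, sigma2 = 1, rho = 0.5, phi = 0.5) {
  smoother_priors(fixed = list(alpha = alpha, sigma2_S = sigma2,
                               rho_s = rho, phi_t = phi, tau2 = tau2))
}

test_that("a large-n observation dominates a small-n one as in the conjugate oracle", {
  g <- make_lattice_adjacency(1, 2)
  obs <- data.frame(survey_id = c("a", "b"), method = "direct",
                    county_id = "C01", year = 2000,
                    q5 = c(0.20, 0.10), n = c(100, 100000))
  tau2 <- c(direct = 0.3)
  fit <- u5m_smooth(obs, g, mcmc = mcmc_control(5000, 1000, 4, seed = 2),
                    priors = fixed_priors(tau2, phi = 0))
  # closed form: prior N(0, Qs^{-1}) with Qs = D - 0.5 W; data precision
  # w_i = log(n_i)/tau2 on cell 1
  w <- log(obs$n) / 0.3
  Qs <- rbind(c(1, -0.5), c(-0.5, 1))
  P <- Qs; P[1, 1] <- P[1, 1] + sum(w)
  mu <- solve(P, c(sum(w * logit(obs$q5)), 0))
  lg <- logit(fit$samples)
  mcmc_mean <- apply(lg, c(2, 3), mean)
  mcmc_se <- apply(lg, c(2, 3), sd) / sqrt(dim(lg)[1])
  expect_true(all(abs(mcmc_mean - mu) < 4 * mcmc_se))
  # posterior sits nearer the large-n observation (log-n weighting keeps the
  # imbalance modest by design: the weight ratio is log(1e5)/log(100) = 2.5)
  post <- invlogit(mcmc_mean[1, 1])
  expect_lt(abs(post - 0.10), abs(post - 0.20))
})

test_that("MCMC conditional means match the dense closed-form solve (KT = 12)", {
  set.seed(31)
  g <- make_lattice_adjacency(2, 2)
  years <- 2001:2003
  alpha <- -2; sigma2 <- 0.8; rho <- 0.7; phi <- 0.6
  tau2 <- c(direct = 0.3, period_MA = 0.5)
  obs <- data.frame(
    survey_id = "s", method = sample(names(tau2), 40, replace = TRUE),
    county_id = sample(g$nodes, 40, replace = TRUE),
    year = sample(years, 40, replace = TRUE),
    q5 = invlogit(rnorm(40, -2, 0.5)), n = sample(50:5000, 40))
  fit <- u5m_smooth(obs, g, years = years,
                    mcmc = mcmc_control(6000, 1000, 5, seed = 4),
                    priors = fixed_priors(tau2, alpha, sigma2, rho, phi))
  ## independent dense oracle
  P0 <- as.matrix(build_precision(g, rho, phi, 3, sigma2))
  cellv <- match(obs$county_id, g$nodes) + (match(obs$year, years) - 1L) * 4L
  w <- log(obs$n) / tau2[obs$method]
  A <- matrix(0, 12, 12); b <- numeric(12)
  for (i in seq_len(40)) {
    A[cellv[i], cellv[i]] <- A[cellv[i], cellv[i]] + w[i]
    b[cellv[i]] <- b[cellv[i]] + w[i] * (logit(obs$q5[i]) - alpha)
  }
  mu <- alpha + solve(P0 + A, b)
  lg <- logit(fit$samples)
  mcmc_mean <- as.vector(apply(lg, c(2, 3), mean))
  mcmc_se <- as.vector(apply(lg, c(2, 3), sd)) / sqrt(dim(lg)[1])
  expect_true(all(abs(mcmc_mean - mu) < 4 * mcmc_se + 1e-8))
})

test_that("the zero-noise limit interpolates the observations", {
  g <- make_lattice_adjacency(2, 2)
  years <- 2001:2003
  set.seed(5)
  obs <- expand.grid(county_id = g$nodes, year = years,
                     stringsAsFactors = FALSE)
  obs$survey_id <- "s"; obs$method <- "direct"
  obs$q5 <- invlogit(rnorm(12, -2, 0.4)); obs$n <- 1000
  fit <- u5m_smooth(obs, g, years = years,
                    mcmc = mcmc_control(3000, 500, 5, seed = 6),
                    priors = fixed_priors(c(direct = 1e-6), alpha = -2,
                                          sigma2 = 1))
  cellv <- match(obs$county_id, g$nodes) + (match(obs$year, years) - 1L) * 4L
  mcmc_mean <- as.vector(apply(logit(fit$samples), c(2, 3), mean))
  expect_lt(max(abs(mcmc_mean[cellv] - logit(obs$q5))), 1e-3)
})

test_that("the sampler is deterministic given its seed", {
  g <- make_lattice_adjacency(1, 2)
  obs <- data.frame(survey_id = "s", method = "direct",
                    county_id = rep(g$nodes, 4), year = rep(2001:2004, 2),
                    q5 = seq(0.08, 0.15, length.out = 8), n = 500)
  f1 <- u5m_smooth(obs, g, mcmc = mcmc_control(1200, 200, 2, seed = 3))
  f2 <- u5m_smooth(obs, g, mcmc = mcmc_control(1200, 200, 2, seed = 3))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$traces, f2$traces)
  f3 <- u5m_smooth(obs, g, mcmc = mcmc_control(1200, 200, 2, seed = 4))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("posterior summaries behave as order statistics require", {
  # constant samples: zero-width interval equal to the constant
  arr_c <- array(0.07, dim = c(200, 2, 2),
                 dimnames = list(NULL, c("A", "B"), 2000:2001))
  s <- summarize_posterior(arr_c)
  expect_true(all(s$mean == 70 & s$lo95 == 70 & s$hi95 == 70))

  # logit-normal cell: mean 0.5 by symmetry, CI bounds at invlogit(+-z)
  set.seed(8)
  z <- rnorm(10000)
  arr_n <- array(invlogit(z), dim = c(10000, 1, 1),
                 dimnames = list(NULL, "A", 2000))
  s2 <- summarize_posterior(arr_n)
  expect_equal(s2$mean / 1000, 0.5, tolerance = 0.01)
  expect_equal(s2$lo95 / 1000, invlogit(qnorm(0.025)), tolerance = 0.02)
  expect_equal(s2$hi95 / 1000, invlogit(qnorm(0.975)), tolerance = 0.02)
  expect_true(all(s2$mean >= s2$lo95 & s2$mean <= s2$hi95))
  expect_error(summarize_posterior(arr_c[1:50, , , drop = FALSE]),
               "at least 100")
})

test_that("smoothing reduces year-on-year roughness below the raw estimates", {
  g <- make_lattice_adjacency(2, 2)
  cfg <- sim_config(g, c(1996, 2010), alpha = -2.2, sigma2_S = 0.3,
                    rho_s = 0.9, phi_t = 0.8, seed = 12)
  surf <- sample_true_surface(cfg)
  obs <- model_sim_obs(surf, g, TAU2_FIVE[c("direct", "period_MA")],
                       n_per_method = 60, seed = 13)
  fit <- u5m_smooth(obs, g, years = surf$years,
                    mcmc = mcmc_control(4000, 1000, 3, seed = 14))
  mn <- apply(fit$samples, c(2, 3), mean)
  rough_fit <- mean(abs(t(diff(t(mn)))))
  raw <- tapply(obs$q5, list(match(obs$county_id, g$nodes), obs$year), mean)
  rough_raw <- mean(abs(diff(t(raw))), na.rm = TRUE)
  expect_lt(rough_fit, rough_raw)

  # model methods surface the fit sensibly
  expect_s3_class(summary(fit), "data.frame")
  expect_true(all(c("alpha", "sigma2_S", "rho_s", "phi_t") %in%
                    names(coef(fit))))
  expect_identical(nrow(predict(fit, counties = "C01")), length(surf$years))
  expect_length(residuals(fit), nrow(obs))
  expect_identical(dim(simulate(fit, nsim = 3, seed = 1))[1], 3L)
})

test_that("removing observations does not shrink the posterior interval", {
  g <- make_lattice_adjacency(1, 2)
  set.seed(15)
  obs <- data.frame(survey_id = "s", method = "direct",
                    county_id = "C01", year = 2000,
                    q5 = invlogit(rnorm(12, -2, 0.2)), n = 800)
  pr <- fixed_priors(c(direct = 0.4), alpha = -2, sigma2 = 0.5, phi = 0)
  mc <- mcmc_control(6000, 1000, 5, seed = 16)
  fit_all <- u5m_smooth(obs, g, years = 2000, mcmc = mc, priors = pr)
  fit_few <- u5m_smooth(obs[1:3, ], g, years = 2000, mcmc = mc, priors = pr)
  wi_all <- diff(unlist(fit_all$summaries[1, c("lo95", "hi95")]))
  wi_few <- diff(unlist(fit_few$summaries[1, c("lo95", "hi95")]))
  expect_gt(wi_few, wi_all * 0.95)  # tolerance for Monte-Carlo noise
})
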