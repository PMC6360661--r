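make_flat_config <- function(q5, women, year = 2000, seed = 3) {
  g <- make_lattice_adjacency(1, 2)
  sim_config(g, c(year - 30L, year), alpha = logit(q5), sigma2_S = 0,
             surveys = list(survey_spec(year, g$nodes, women)), seed = seed)
}

test_that("a zero-mortality surface produces no child deaths", {
  cfg <- make_flat_config(0.5, 300)
  surf <- sample_true_surface(cfg)
  surf$Q[] <- 0  # hand-built degenerate truth
  rec <- simulate_survey(cfg, surf, 1)
  expect_gt(nrow(rec$children), 0)
  expect_true(all(is.na(rec$children$death_age_months)))
})

test_that("identical configuration and seed give bit-identical records", {
  cfg <- make_flat_config(0.1, 200)
  surf <- sample_true_surface(cfg)
  r1 <- simulate_survey(cfg, surf, 1)
  r2 <- simulate_survey(cfg, surf, 1)
  expect_identical(r1, r2)
  r3 <- simulate_survey(cfg, surf, 1, seed = 99)
  expect_false(identical(r1$children, r3$children))
})

test_that("simulated records respect the interview and age invariants", {
  cfg <- make_flat_config(0.15, 500)
  surf <- sample_true_surface(cfg)
  rec <- simulate_survey(cfg, surf, 1)
  age <- rec$women$interview_month - rec$women$birth_month
  expect_true(all(age >= 15 * 12 & age < 50 * 12))
  expect_true(all(rec$children$birth_month <= rec$children$interview_month))
  d <- rec$children$death_age_months
  obs <- !is.na(d)
  expect_true(all(d[obs] >= 0 & d[obs] <= 59))
  # observed deaths happen no later than the interview month
  expect_true(all(rec$children$birth_month[obs] + d[obs] <=
                    rec$children$interview_month[obs]))
  expect_error(simulate_survey(cfg, surf, 2), "out of range")
})

test_that("children die before age five with probability Q (consistency)", {
  q5 <- 0.12
  cfg <- make_flat_config(q5, 8000, seed = 11)
  surf <- sample_true_surface(cfg)
  rec <- simulate_survey(cfg, surf, 1)
  ch <- rec$children
  full <- ch[ch$interview_month - ch$birth_month >= 60, ]
  expect_gt(nrow(full), 20000)
  p_hat <- mean(!is.na(full$death_age_months))
  se <- sqrt(q5 * (1 - q5) / nrow(full))
  expect_lt(abs(p_hat - q5), 3 * se)

  # and the direct estimator recovers Q on the simulated output
  est <- q5_direct(tabulate_exposure(rec))
  est <- est[est$defined & est$exposure_months > 50000, ]
  expect_lt(abs(mean(est$q5) - q5), 0.01)
})

test_that("deaths are allocated across age segments by hazard_split", {
  split <- c(0.35, 0.30, 0.15, 0.10, 0.06, 0.04)
  cfg <- make_flat_config(0.25, 6000, seed = 21)
  surf <- sample_true_surface(cfg)
  rec <- simulate_survey(cfg, surf, 1)
  ch <- rec$children
  full <- ch[ch$interview_month - ch$birth_month >= 60 &
               !is.na(ch$death_age_months), ]
  seg <- findInterval(full$death_age_months, c(0, 1, 12, 24, 36, 48))
  obs <- tabulate(seg, 6) / nrow(full)
  se <- sqrt(split * (1 - split) / nrow(full))
  expect_true(all(abs(obs - split) < 4 * se))
})
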