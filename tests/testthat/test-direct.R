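test_that("a fully observed surviving child yields the canonical exposure", {
  # child aged 70 months at interview, well inside one 96-month period
  fx <- fix_woman("w1", 30, list(c(70L, NA)))
  tab <- tabulate_exposure(bind_cbh(fx), period_months = 96L)
  expect_identical(ncol(tab$E), 1L)
  expect_equal(tab$E[, 1], c(1, 11, 12, 12, 12, 12))
  expect_true(all(tab$D == 0))
})

test_that("a death at six months lands in segment 2 with the right exposure", {
  fx <- fix_woman("w1", 30, list(c(20L, 6L)))
  tab <- tabulate_exposure(bind_cbh(fx), period_months = 96L)
  expect_equal(tab$D[, 1], c(0, 1, 0, 0, 0, 0))
  expect_equal(tab$E[, 1], c(1, 6, 0, 0, 0, 0))
})

test_that("tabulation matches the per-child-month brute-force oracle", {
  rec <- random_cbh(500, seed = 17)
  tab <- tabulate_exposure(rec)
  orc <- oracle_exposure(rec)
  expect_equal(unname(tab$E), orc$E)
  expect_equal(unname(tab$D), orc$D)
  # exposure conservation: at most 60 months per child
  expect_lte(sum(tab$E), 60 * nrow(rec$children))
})

test_that("q5 follows the closed form at uniform monthly risk", {
  E <- matrix(c(100, 1100, 1200, 1200, 1200, 1200) * 50, ncol = 1)
  tab <- structure(list(D = E * 0.01, E = E,
                        periods = data.frame(period = 0L, midpoint_year = 2000L),
                        period_months = 24L, n_women = 1L, n_children = 1L),
                   class = "exposure_table")
  est <- q5_direct(tab)
  expect_equal(est$q5, 1 - 0.99^60, tolerance = 1e-12)

  # boundary cases: no deaths, and certain death in month 0
  tab$D <- E * 0
  expect_equal(q5_direct(tab)$q5, 0)
  tab$D <- E * 0; tab$D[1, 1] <- E[1, 1]
  expect_equal(q5_direct(tab)$q5, 1)
})

test_that("adding a death never decreases q5 and zero exposure is flagged", {
  set.seed(4)
  E <- matrix(rpois(12, 800) + 60, 6, 2)
  D <- matrix(rbinom(12, 50, 0.3), 6, 2)
  tab <- structure(list(D = D, E = E,
                        periods = data.frame(period = 0:1,
                                             midpoint_year = c(2000L, 1998L)),
                        period_months = 24L, n_women = 1L, n_children = 1L),
                   class = "exposure_table")
  base <- q5_direct(tab)$q5
  for (s in 1:6) {
    tab2 <- tab
    tab2$D[s, 1] <- tab2$D[s, 1] + 1
    expect_gte(q5_direct(tab2)$q5[1], base[1])
  }
  tab$E[3, 2] <- 0; tab$D[3, 2] <- 0
  est <- q5_direct(tab)
  expect_false(est$defined[2])
  expect_true(is.na(est$q5[2]))
  expect_true(est$defined[1])
})

test_that("out-of-range death ages are rejected explicitly", {
  fx <- fix_woman("w1", 30, list(c(80L, 65L)))
  expect_error(tabulate_exposure(bind_cbh(fx)), "outside 0-59")
})

test_that("estimate_direct emits the smoother's observation schema", {
  g <- make_lattice_adjacency(1, 2)
  cfg <- sim_config(g, c(1985, 2005), alpha = -2,
                    surveys = list(survey_spec(2005, g$nodes, 800)), seed = 2)
  rec <- simulate_survey(cfg, sample_true_surface(cfg), 1)
  est <- estimate_direct(rec)
  expect_true(all(c("survey_id", "method", "county_id", "year", "q5", "n")
                  %in% names(est)))
  expect_true(all(est$q5 > 0 & est$q5 < 1))
  expect_true(all(est$method == "direct"))
  expect_setequal(unique(est$county_id), g$nodes)
  # capped at 25 years before the interview
  expect_true(all(est$year >= 2005 - 25))
})
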