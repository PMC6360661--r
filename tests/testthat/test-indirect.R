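ma_sbh <- function(women, ceb, cd, iy = 2010) {
  labels <- paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
  structure(data.frame(county_id = "all", group_label = labels,
                       women = women, ceb = ceb, cd = cd,
                       stringsAsFactors = FALSE),
            class = c("sbh_table", "data.frame"), grouping = "MA",
            interview_year = iy)
}

identity_cohort <- function() {
  labels <- paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")
  cohort_coefficients(data.frame(
    group_label = labels, beta0 = 0, beta1 = 1, beta2 = 0, beta3 = 0,
    beta4 = 0, u = 0, ref_offset = seq(1, 16, length.out = 7)), "MA")
}

test_that("parity ratios reproduce hand-computed values", {
  tab <- ma_sbh(women = rep(100L, 7),
                ceb = c(20L, 100L, 250L, 300L, 320L, 330L, 335L),
                cd = c(2L, 10L, 25L, 30L, 32L, 33L, 33L))
  r <- parity_ratios(tab)
  expect_equal(unname(r), c(0.2 / 1.0, 1.0 / 2.5))

  tab2 <- ma_sbh(rep(10L, 7), rep(30L, 7), rep(3L, 7))
  expect_equal(unname(parity_ratios(tab2)), c(1, 1))

  tab3 <- tab; tab3$ceb[2] <- 0L
  expect_error(parity_ratios(tab3), "zero denominator")
})

test_that("identity coefficients return the raw proportion dead exactly", {
  tab <- ma_sbh(women = rep(50L, 7),
                ceb = c(10L, 60L, 120L, 160L, 180L, 190L, 200L),
                cd = c(1L, 7L, 15L, 22L, 27L, 30L, 35L))
  out <- cohort_q5(tab, identity_cohort(), c(ratio_1 = 0.3, ratio_2 = 0.5))
  expect_equal(out$q5, tab$cd / tab$ceb)
  expect_equal(out$reference_year, 2010 - identity_cohort()$ref_offset)
})

test_that("groups without usable deaths are skipped with a message", {
  tab <- ma_sbh(women = rep(50L, 7),
                ceb = c(10L, 60L, 120L, 160L, 180L, 190L, 200L),
                cd = c(0L, 7L, 15L, 22L, 27L, 30L, 35L))
  expect_message(out <- cohort_q5(tab, identity_cohort(), c(1, 1)),
                 "skipping")
  expect_false("15-19" %in% out$group_label)
  expect_identical(nrow(out), 6L)
})

test_that("a populated group without a coefficient row is an error", {
  tab <- ma_sbh(rep(50L, 7), rep(100L, 7), rep(10L, 7))
  cc <- identity_cohort()
  cc2 <- cohort_coefficients(as.data.frame(cc)[-3, ], "MA")
  expect_error(cohort_q5(tab, cc2, c(1, 1)), "missing coefficient row")
})

test_that("redistribution spreads totals and conserves them", {
  dist <- empirical_distribution(data.frame(
    group_label = "20-24", years_before = 0:4,
    birth_p = rep(0.2, 5), death_p = rep(0.2, 5)), "MA")
  tab <- ma_sbh(c(0L, 100L, rep(0L, 5)), c(0L, 100L, rep(0L, 5)),
                c(0L, 20L, rep(0L, 5)))
  out <- period_redistribute(tab, dist)
  expect_equal(out$ceb, rep(20, 5))
  expect_equal(out$cd, rep(4, 5))

  # two groups with distinct distributions: hand-computed mixture
  dist2 <- empirical_distribution(data.frame(
    group_label = rep(c("20-24", "25-29"), each = 3),
    years_before = rep(0:2, 2),
    birth_p = c(0.5, 0.3, 0.2, 0.1, 0.4, 0.5),
    death_p = c(0.6, 0.3, 0.1, 0.2, 0.3, 0.5)), "MA")
  tab2 <- ma_sbh(c(0L, 10L, 10L, rep(0L, 4)), c(0L, 100L, 200L, rep(0L, 4)),
                 c(0L, 10L, 40L, rep(0L, 4)))
  out2 <- period_redistribute(tab2, dist2)
  expect_equal(out2$ceb, c(100 * 0.5 + 200 * 0.1, 100 * 0.3 + 200 * 0.4,
                           100 * 0.2 + 200 * 0.5))
  expect_equal(out2$cd, c(10 * 0.6 + 40 * 0.2, 10 * 0.3 + 40 * 0.3,
                          10 * 0.1 + 40 * 0.5))
  expect_lt(abs(sum(out2$ceb) - 300), 1e-9)
  expect_lt(abs(sum(out2$cd) - 50), 1e-9)

  bad <- dist
  bad$birth_p[1] <- 0.5
  expect_error(period_redistribute(tab, bad), "does not sum to 1")
})

test_that("period conversion is the identity under identity coefficients", {
  pc <- period_coefficients(data.frame(years_before = 0:24, beta0 = 0,
                                       beta1 = 1, u = 0), "MA")
  py <- data.frame(years_before = 0:3, ceb = c(100, 80, 60, 40),
                   cd = c(10, 0, 9, 8))
  out <- period_q5(py, pc, 2010)
  expect_equal(out$q5, c(0.1, 0.15, 0.2))   # cd = 0 year skipped
  expect_equal(out$year, c(2010, 2008, 2007))
  # beyond-horizon years are dropped
  py2 <- data.frame(years_before = c(2, 30), ceb = c(50, 50), cd = c(5, 5))
  expect_identical(nrow(period_q5(py2, pc, 2010)), 1L)
})
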