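# a small shared corpus keeps these structural checks fast; the full-size
# recovery experiment lives in the acceptance suite
small_corpus <- local({
  corpus <- NULL
  function() {
    if (is.null(corpus))
      corpus <<- make_calibration_corpus(n_surveys = 20, women = 1500,
                                         seed = 7)
    corpus
  }
})

test_that("calibration produces complete, well-formed coefficient tables", {
  cal <- suppressWarnings(calibrate_coefficients(small_corpus()))
  expect_s3_class(cal, "u5m_coefficients")
  for (nm in c("cohort_MA", "cohort_TFB")) {
    cc <- cal[[nm]]
    expect_true(all(is.finite(cc$beta0)) && all(is.finite(cc$beta1)))
    expect_false(is.unsorted(cc$ref_offset))
    expect_lte(max(cc$ref_offset), 18)
    expect_true(all(cc$u == 0))
  }
  # the proportion-dead slope should be the dominant, near-unit regressor
  central <- cal$cohort_MA$group_label %in% c("20-24", "25-29", "30-34")
  expect_true(all(abs(cal$cohort_MA$beta1[central] - 1) < 0.5))
  expect_true(all(cal$period_MA$years_before <= 24))
  # recent years need a large positive intercept correction (children have
  # had little time at risk), decaying toward zero further back
  expect_gt(cal$period_MA$beta0[cal$period_MA$years_before == 0], 0.3)
  expect_lt(abs(cal$period_MA$beta0[cal$period_MA$years_before == 10]), 0.3)
})

test_that("empirical distributions are proper per group", {
  cal <- suppressWarnings(calibrate_coefficients(small_corpus()))
  for (nm in c("dist_MA", "dist_TFB")) {
    d <- cal[[nm]]
    expect_true(all(d$birth_p >= 0 & d$death_p >= 0))
    for (g in unique(d$group_label)) {
      expect_equal(sum(d$birth_p[d$group_label == g]), 1, tolerance = 1e-12)
      expect_equal(sum(d$death_p[d$group_label == g]), 1, tolerance = 1e-12)
    }
  }
})

test_that("coefficient bundles round-trip through CSV", {
  cal <- suppressWarnings(calibrate_coefficients(small_corpus()))
  dir <- withr::local_tempdir()
  write_coefficients(cal, dir)
  cal2 <- read_coefficients(dir)
  for (nm in c("cohort_MA", "cohort_TFB", "period_MA", "period_TFB"))
    expect_equal(as.data.frame(cal[[nm]]), as.data.frame(cal2[[nm]]),
                 tolerance = 1e-12)
  expect_identical(attr(cal2$cohort_MA, "grouping"), "MA")
})

test_that("the packaged default coefficients load and convert sensibly", {
  cal <- default_coefficients()
  expect_s3_class(cal, "u5m_coefficients")
  # identity sanity: converting a mid-range proportion gives a mid-range q5
  tab <- structure(data.frame(county_id = "all",
                              group_label = cal$cohort_MA$group_label,
                              women = 500L,
                              ceb = as.integer(round(500 * c(0.3, 1.3, 2.6, 3.9, 5, 5.6, 5.9))),
                              cd = NA_integer_, stringsAsFactors = FALSE),
                   class = c("sbh_table", "data.frame"), grouping = "MA",
                   interview_year = 2010)
  tab$cd <- as.integer(round(tab$ceb * 0.1))
  out <- cohort_q5(tab, cal$cohort_MA, parity_ratios(tab))
  expect_true(all(out$q5 > 0.05 & out$q5 < 0.3))
})
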