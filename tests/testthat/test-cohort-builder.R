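test_that("age at draw is an exact calendar-day count", {
  expect_identical(age_at_draw("2010-01-01", "2010-01-31"), 30L)
  expect_identical(age_at_draw("2010-01-01", "2010-01-01"), 0L)
  expect_identical(age_at_draw("2004-02-29", "2018-02-28"), 5113L)
  expect_error(age_at_draw("2010-01-02", "2010-01-01"),
               class = "creatref_validation_error")
})

test_that("default strata: 36 half-open windows tiling [30 d, 18 y) per sex", {
  g <- default_groups()
  expect_identical(nrow(g), 36L)
  expect_identical(sum(g$sex == "M"), 18L)
  expect_identical(sum(g$sex == "F"), 18L)
  for (s in c("M", "F")) {
    win <- g[g$sex == s, ]
    win <- win[order(win$age_min_days), ]
    expect_equal(win$age_min_days[1], 30)
    expect_equal(win$age_max_days[nrow(win)], 18 * 365.25)
    # contiguity: each window starts exactly where the previous one ends
    expect_equal(win$age_min_days[-1], win$age_max_days[-nrow(win)])
  }
  expect_identical(g$label[g$sex == "M"][1], "Infant (1-12 months)")
})

test_that("stratum assignment respects the half-open boundary convention", {
  expect_identical(assign_group(180, "M"), "Infant (1-12 months)")
  expect_identical(assign_group(20, "F"), NA_character_)      # neonate
  expect_identical(assign_group(365.25 * 14, "M"), "14-15 years")  # lower bound inclusive
  expect_identical(assign_group(365.25 * 18, "M"), NA_character_)  # 18th birthday out
  expect_identical(assign_group(365, "F"), "Infant (1-12 months)") # whole-day 365 covered

  overlapping <- tibble::tibble(
    label = c("a", "b"), sex = "M",
    age_min_days = c(0, 50), age_max_days = c(100, 150)
  )
  expect_error(assign_group(60, "M", overlapping),
               class = "creatref_integrity_error")
})

test_that("single-measurement selection excludes individuals, not records", {
  recs <- make_records(c("A", "B", "B", "B"),
                       draw = c("2012-01-01", "2012-01-01", "2012-02-01", "2012-03-01"))
  sel <- select_single_measurement(recs)
  expect_identical(sel$records$individual_id, "A")
  expect_identical(sel$n_excluded_individuals, 1L)

  all_single <- make_records(c("A", "B", "C"))
  sel2 <- select_single_measurement(all_single)
  expect_identical(sel2$records, all_single)
  expect_identical(sel2$n_excluded_individuals, 0L)

  # same-day duplicates count as multiple unless collapsed
  dup <- make_records(c("A", "A"), draw = "2012-01-01")
  expect_identical(nrow(select_single_measurement(dup)$records), 0L)
  expect_identical(nrow(select_single_measurement(dup, collapse_same_day = TRUE)$records), 1L)
})

test_that("kept fraction tracks 1 - p_multi within 3 binomial standard errors", {
  cfg <- synthetic_cohort_config(n_individuals = 5000, seed = 7)
  recs <- generate_cohort(cfg)
  sel <- select_single_measurement(recs)
  p_hat <- nrow(sel$records) / cfg$n_individuals
  se <- sqrt(cfg$p_multi * (1 - cfg$p_multi) / cfg$n_individuals)
  expect_lt(abs(p_hat - (1 - cfg$p_multi)), 3 * se)
})

test_that("build_cohort handles the empty and single-record cases", {
  empty <- make_records(character(0))[0, ]
  cohort <- build_cohort(empty)
  expect_identical(nrow(cohort$groups), 36L)
  expect_true(all(lengths(cohort$groups$values) == 0))
  expect_identical(cohort$flow$n_single_measurement, 0L)

  one <- make_records("A", sex = "M", birth = "2011-06-01", draw = "2011-12-01",
                      creatinine = 0.25)
  cohort1 <- build_cohort(one)
  nonempty <- lengths(cohort1$groups$values) > 0
  expect_identical(sum(nonempty), 1L)
  expect_identical(cohort1$groups$label[nonempty], "Infant (1-12 months)")
  expect_identical(cohort1$groups$sex[nonempty], "M")
  expect_equal(cohort1$groups$values[nonempty][[1]], 0.25)

  expect_error(build_cohort(make_records("A", sex = "U")),
               class = "creatref_validation_error")
})

test_that("cohort build conserves records, is order-invariant, and keeps ids unique", {
  recs <- generate_cohort(synthetic_cohort_config(n_individuals = 3000, seed = 11))
  cohort <- build_cohort(recs)
  # partition property: every kept record in exactly one stratum
  expect_identical(sum(lengths(cohort$groups$values)), cohort$flow$n_single_measurement)
  expect_identical(anyDuplicated(cohort$records$individual_id), 0L)

  shuffled <- recs[sample.int(nrow(recs)), ]
  cohort2 <- build_cohort(shuffled)
  expect_identical(cohort2$flow, cohort$flow)
  expect_equal(lapply(cohort2$groups$values, sort),
               lapply(cohort$groups$values, sort))
})
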