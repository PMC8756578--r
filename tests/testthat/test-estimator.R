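test_that("group statistics use the sample (n-1) standard deviation", {
  st <- group_statistics(c(0.2, 0.4))
  expect_identical(st$n, 2L)
  expect_equal(st$mean, 0.3)
  expect_equal(st$sd, sqrt(0.02))
  expect_equal(group_statistics(rep(0.5, 6))$sd, 0)
  expect_true(is.na(group_statistics(0.5)$sd))
  expect_error(group_statistics(numeric(0)), class = "creatref_domain_error")
})

test_that("parametric limits are mean +/- z SD and symmetric about the mean", {
  pl <- parametric_limits(0.25, 0.07)
  expect_equal(pl$lower, 0.1128)
  expect_equal(pl$upper, 0.3872)
  expect_equal(parametric_limits(0.5, 0), tibble::tibble(lower = 0.5, upper = 0.5))
  expect_error(parametric_limits(0.5, -0.1), class = "creatref_domain_error")

  withr::local_seed(3)
  m <- runif(20, 0.2, 1)
  s <- runif(20, 0, 0.2)
  pl <- parametric_limits(m, s, 1.96)
  expect_equal(pl$lower + pl$upper, 2 * m)
})

test_that("limit rounding is half-away-from-zero and idempotent", {
  expect_equal(round_limit(0.7864), 0.79)
  expect_equal(round_limit(0.125), 0.13)
  expect_equal(round_limit(0.145), 0.15)
  expect_equal(round_limit(-0.125), -0.13)
  expect_equal(round_limit(2.5, 0), 3)
  x <- c(0.1128, 0.3872, 0.6468, -0.005, 0)
  expect_equal(round_limit(round_limit(x)), round_limit(x))
})

test_that("empirical percentiles match the sort-and-interpolate rule", {
  x <- seq_len(40) / 10
  el <- empirical_limits(x)
  expect_equal(unname(el), bf_quantile(x, c(0.025, 0.975)))
  expect_equal(empirical_limits(rep(0.4, 50)), c(lower = 0.4, upper = 0.4))

  # large clean normal sample: empirical and parametric limits agree
  withr::local_seed(8)
  y <- rnorm(1e5, 0.5, 0.07)
  st <- group_statistics(y)
  pl <- parametric_limits(st$mean, st$sd)
  el <- empirical_limits(y)
  expect_lt(abs(el[["lower"]] - pl$lower), 0.01)
  expect_lt(abs(el[["upper"]] - pl$upper), 0.01)
})

test_that("estimate_all yields one estimate per non-empty stratum with consistent flow", {
  recs <- generate_cohort(synthetic_cohort_config(n_individuals = 3000, seed = 17))
  cohort <- build_cohort(recs)
  res <- estimate_all(cohort)
  est <- res$estimates
  expect_identical(nrow(est), sum(lengths(cohort$groups$values) > 0))
  # per-group n equals the post-fence kept count
  expect_identical(est$n + est$n_outliers_removed,
                   lengths(cohort$groups$values)[lengths(cohort$groups$values) > 0])
  expect_identical(res$flow$n_final,
                   res$flow$n_single_measurement - res$flow$n_outliers_removed)
  expect_identical(res$flow$n_final, res$flow$n_final_male + res$flow$n_final_female)
  expect_identical(est$meets_min_n, est$n >= 120L)

  tiny <- build_cohort(generate_cohort(synthetic_cohort_config(n_individuals = 30, seed = 1)))
  expect_warning(estimate_all(tiny), "empty group")
})

test_that("adding a constant shifts mean, limits, and fence by exactly that constant", {
  withr::local_seed(19)
  x <- rnorm(200, 0.5, 0.08)
  c_ <- 0.37
  fr <- remove_upper_outliers(x)
  frc <- remove_upper_outliers(x + c_)
  expect_equal(frc$upper_fence, fr$upper_fence + c_)
  expect_identical(frc$n_removed, fr$n_removed)
  st <- group_statistics(fr$kept)
  stc <- group_statistics(frc$kept)
  expect_equal(stc$mean, st$mean + c_)
  expect_equal(stc$sd, st$sd)
  expect_equal(parametric_limits(stc$mean, stc$sd)$upper,
               parametric_limits(st$mean, st$sd)$upper + c_)
})

test_that("reversion detection flags exactly the age bins whose URL drops", {
  fix <- external_url_series()$uemura_f
  expect_identical(detect_reversions(fix$urls, fix$labels), fix$marked)

  tab <- default_group_params()
  male <- tab[tab$sex == "M", ]
  expect_identical(detect_reversions(male$p97_5, male$label), character(0))

  expect_identical(detect_reversions(c(0.3, 0.4, 0.5)), character(0))
  expect_identical(detect_reversions(0.5), character(0))
})

test_that("adolescent male-female URL differences summarise correctly", {
  tab <- default_group_params()
  tab$url <- tab$p97_5
  d <- sex_url_differences(tab, age_floor_years = 13)
  expect_identical(cents(d$min), 11L)
  expect_identical(cents(d$max), 23L)
  expect_identical(nrow(d$differences), 5L)

  same <- tab
  same$url[same$sex == "F"] <- same$url[same$sex == "M"]
  ds <- sex_url_differences(same, 13)
  expect_equal(c(ds$min, ds$max), c(0, 0))

  one <- tab[tab$label == "16-17 years", ]
  d1 <- sex_url_differences(one, 13)
  expect_identical(cents(d1$max), 23L)

  expect_error(sex_url_differences(tab[tab$sex == "M", ], 13),
               class = "creatref_domain_error")
})

test_that("sensitivity comparison is all-true on identical inputs and robust to random flags", {
  recs <- generate_cohort(clean_config(seed = 23))
  est <- suppressWarnings(estimate_all(build_cohort(recs)))$estimates
  self <- sensitivity_compare(est, est)
  expect_true(self$all_agree)
  expect_equal(self$excluded_fraction, 0)

  flagged <- unique(recs$individual_id[recs$kidney_dx])
  restricted <- recs[!recs$individual_id %in% flagged, ]
  est_r <- suppressWarnings(estimate_all(build_cohort(restricted)))$estimates
  comp <- sensitivity_compare(est, est_r)
  # flags are independent of value, so rounded means/SDs should rarely move
  expect_gte(comp$n_agree, 30L)
  p <- 0.021
  se <- sqrt(p * (1 - p) / sum(est$n))
  expect_lt(abs(comp$excluded_fraction - p), 3 * se + 0.001)

  expect_error(sensitivity_compare(est, est_r[-1, ]),
               class = "creatref_domain_error")
})
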