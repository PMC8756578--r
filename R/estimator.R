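#' Per-group descriptive statistics
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator, the
#' spreadsheet STDEV convention). With a single value the SD is `NA`.
#'
#' @param values Non-empty numeric vector.
#' @return Named list `n`, `mean`, `sd`.
#' @export
group_statistics <- function(values) {
  if (!length(values)) {
    abort("Cannot summarise an empty group.", class = "creatref_domain_error")
  }
  list(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2) sd(values) else NA_real_
  )
}

#' Parametric central-95% reference limits
#'
#' Normal-theory limits mean +/- z*SD, unrounded. With the default z = 1.96
#' these are the parametric P2.5 and P97.5.
#'
#' @param mean,sd Numeric vectors (mg/dL), recycled; `sd` must be >= 0.
#' @param z Normal multiplier, default 1.96.
#' @return A tibble with columns `lower` and `upper`.
#' @export
#' @examples
#' parametric_limits(0.25, 0.07)  # 0.1128, 0.3872
parametric_limits <- function(mean, sd, z = 1.96) {
  if (any(sd < 0, na.rm = TRUE)) {
    abort("`sd` must be non-negative.", class = "creatref_domain_error")
  }
  tibble::tibble(lower = mean - z * sd, upper = mean + z * sd)
}

#' Empirical P2.5 and P97.5
#'
#' Order-statistic percentiles at 2.5% and 97.5% under the configured
#' interpolation rule. Samples below ~40 values cannot pin the outer 2.5%
#' tails; callers should rely on the adequacy flag for such groups.
#'
#' @inheritParams quartiles
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
empirical_limits <- function(values, method = c("linear", "hinges", "nearest")) {
  type <- .match_quantile_method(method)
  if (!length(values)) {
    abort("`values` must be non-empty.", class = "creatref_domain_error")
  }
  q <- quantile(values, c(0.025, 0.975), type = type, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Round a reported limit
#'
#' Half-away-from-zero decimal rounding (the spreadsheet/clinical-reporting
#' convention, unlike R's round-half-even), guarded against binary
#' representation noise.
#'
#' @param x Numeric vector.
#' @param decimals Non-negative integer, default 2.
#' @return `x` rounded to `decimals` places.
#' @export
#' @examples
#' round_limit(0.125)   # 0.13, not 0.12
#' round_limit(0.7864)  # 0.79
round_limit <- function(x, decimals = 2) {
  stopifnot(is.numeric(x), decimals >= 0)
  f <- 10^decimals
  scaled <- abs(x) * f
  pos <- which(is.finite(scaled) & scaled > 0)
  scaled[pos] <- signif(scaled[pos], 15)
  sign(x) * floor(scaled + 0.5) / f
}

#' Estimate reference limits for every stratum
#'
#' Runs the per-group stages on a built cohort: upper-fence trimming, mean/SD,
#' parametric limits (mean +/- z*SD), empirical percentiles, and the IFCC
#' adequacy flag, then completes the enrollment flow summary. Empty strata are
#' omitted with a warning.
#'
#' @param cohort A `creat_cohort` from [build_cohort()].
#' @param config A [pipeline_config()].
#' @return A list: `estimates` (tibble, one row per non-empty stratum:
#'   `label`, `sex`, `age_min_days`, `age_max_days`, `n`, `mean`, `sd`,
#'   `p2_5_param`, `p97_5_param`, `p2_5_emp`, `p97_5_emp`,
#'   `n_outliers_removed`, `meets_min_n`) and `flow` (completed
#'   [flow_summary()]). Means, SDs and limits are unrounded; rounding is a
#'   reporting concern (see [write_reference_table()]).
#' @export
estimate_all <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "creat_cohort"))
  g <- cohort$groups
  empty <- lengths(g$values) == 0L
  if (any(empty)) {
    warn(sprintf("%d empty group(s) omitted from estimates.", sum(empty)))
  }
  rows <- purrr::pmap(
    g[!empty, ],
    function(label, sex, age_min_days, age_max_days, values) {
      fr <- remove_upper_outliers(values, config$fence_multiplier,
                                  config$quantile_method, config$outlier_floor_n)
      st <- group_statistics(fr$kept)
      pl <- parametric_limits(st$mean, st$sd, config$z_value)
      el <- empirical_limits(fr$kept, config$quantile_method)
      tibble::tibble(
        label = label, sex = sex,
        age_min_days = age_min_days, age_max_days = age_max_days,
        n = st$n, mean = st$mean, sd = st$sd,
        p2_5_param = pl$lower, p97_5_param = pl$upper,
        p2_5_emp = el[["lower"]], p97_5_emp = el[["upper"]],
        n_outliers_removed = fr$n_removed,
        meets_min_n = st$n >= config$min_group_n
      )
    }
  )
  estimates <- dplyr::bind_rows(rows)

  flow <- cohort$flow
  flow$n_outliers_removed <- sum(estimates$n_outliers_removed)
  flow$n_final <- sum(estimates$n)
  flow$n_final_male <- sum(estimates$n[estimates$sex == "M"])
  flow$n_final_female <- sum(estimates$n[estimates$sex == "F"])
  .validate_flow(flow)

  list(estimates = estimates, flow = flow)
}

#' Detect reversion points in an age-ordered URL sequence
#'
#' Serum creatinine tracks muscle mass and rises monotonically with age in
#' children, so the upper reference limit of an older bin should never fall
#' below its predecessor's. A "reversion point" is an age bin whose URL is
#' strictly lower than the preceding bin's — typically a symptom of
#' under-sized strata.
#'
#' @param urls Numeric URL sequence ordered by ascending age, one sex.
#' @param labels Age-bin labels matching `urls`; defaults to positions.
#' @return Character vector of labels where the URL reverts (empty iff the
#'   sequence is non-decreasing).
#' @export
#' @examples
#' detect_reversions(c(0.53, 0.50, 0.57), c("8-9 years", "9-10 years", "10-11 years"))
detect_reversions <- function(urls, labels = NULL) {
  labels <- labels %||% as.character(seq_along(urls))
  stopifnot(length(labels) == length(urls))
  if (length(urls) < 2) {
    return(character(0))
  }
  labels[which(diff(urls) < 0) + 1L]
}

#' Adolescent male-female URL differences
#'
#' For every age bin at or above `age_floor_years` present for both sexes,
#' the male minus female upper reference limit (on reported, i.e. rounded,
#' values), plus the range extremes. Androgen-driven muscle-mass growth makes
#' these differences positive and widening through adolescence.
#'
#' @param estimates Tibble with `label`, `sex`, `age_min_days`, and either a
#'   `url` column (already-rounded URLs, e.g. a published reference table's
#'   `p97_5`) or `p97_5_param`, which is rounded to `decimals`.
#' @param age_floor_years Lower age bound in years; default 13 (adolescence).
#' @param decimals Reporting decimals used when rounding `p97_5_param`.
#' @return List: `min`, `max`, and `differences` (tibble with per-bin URLs
#'   and `diff`).
#' @export
sex_url_differences <- function(estimates, age_floor_years = 13, decimals = 2) {
  est <- tibble::as_tibble(estimates)
  if (!"url" %in% names(est)) {
    est$url <- round_limit(est$p97_5_param, decimals)
  }
  est <- est[est$age_min_days >= age_floor_years * 365.25, ]
  wide <- tidyr::pivot_wider(
    dplyr::select(est, "label", "age_min_days", "sex", "url"),
    names_from = "sex", values_from = "url"
  )
  if (!all(c("M", "F") %in% names(wide)) || anyNA(wide$M) || anyNA(wide$F)) {
    abort("Every age bin above the floor needs both sexes.",
          class = "creatref_domain_error")
  }
  wide <- dplyr::arrange(wide, .data$age_min_days)
  wide$diff <- wide$M - wide$F
  list(min = min(wide$diff), max = max(wide$diff),
       differences = dplyr::select(wide, "label", male_url = "M",
                                   female_url = "F", "diff"))
}

#' Diagnosis-flag sensitivity comparison
#'
#' Compares the full-cohort estimates with estimates recomputed after
#' excluding flagged (kidney/urinary diagnosis) individuals: for each stratum,
#' do mean and SD agree once rounded to reporting precision? If the indirect
#' design worked, the residual flagged fraction is too small to move any
#' rounded value.
#'
#' @param full,restricted Estimate tibbles from [estimate_all()] covering the
#'   same strata.
#' @param decimals Reporting decimals; default 2.
#' @return List: `by_group` (tibble with `agree_mean`, `agree_sd`, `agree`),
#'   `n_agree`, `all_agree`, and `excluded_fraction` (share of full-cohort
#'   individuals dropped in the restricted run).
#' @export
sensitivity_compare <- function(full, restricted, decimals = 2) {
  j <- dplyr::full_join(
    dplyr::select(full, "label", "sex", full_n = "n", full_mean = "mean", full_sd = "sd"),
    dplyr::select(restricted, "label", "sex", res_n = "n", res_mean = "mean", res_sd = "sd"),
    by = c("label", "sex")
  )
  if (anyNA(j$full_n) || anyNA(j$res_n)) {
    abort("Estimate sets do not cover the same strata.",
          class = "creatref_domain_error")
  }
  j$agree_mean <- round_limit(j$full_mean, decimals) == round_limit(j$res_mean, decimals)
  j$agree_sd <- round_limit(j$full_sd, decimals) == round_limit(j$res_sd, decimals)
  j$agree <- j$agree_mean & j$agree_sd
  list(
    by_group = dplyr::select(j, "label", "sex", "agree_mean", "agree_sd", "agree"),
    n_agree = sum(j$agree),
    all_agree = all(j$agree),
    excluded_fraction = 1 - sum(j$res_n) / sum(j$full_n)
  )
}
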