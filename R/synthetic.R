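#' Synthetic EHR cohort configuration
#'
#' Parameters of the synthetic electronic-health-record creatinine cohort.
#' The defaults emulate the population the pipeline is designed for: ~44,197
#' children producing ~151,859 measurements, of whom 28,595 have a single
#' measurement; repeat-measured individuals (renal follow-up) average ~7.9
#' draws; 20% of them carry a persistent multiplicative creatinine elevation
#' (AKI/CKD model, median factor 2); 2.1% of healthy single-measurement
#' individuals carry an incidental kidney/urinary diagnosis flag independent
#' of their creatinine value.
#'
#' @param n_individuals Number of individuals; default 44,197.
#' @param group_params Per-stratum truth: tibble with `label`, `sex`,
#'   `age_min_days`, `age_max_days`, `n` (sampling weight), `mean`, `sd`
#'   (mg/dL). Default [default_group_params()]. Must cover every stratum of
#'   [default_groups()].
#' @param p_multi Probability an individual is repeat-measured; default
#'   1 - 28595/44197 (~0.353).
#' @param repeat_count_law Distribution of per-individual measurement counts
#'   for repeat-measured individuals: `list(type = "constant", count = k)` or
#'   `list(type = "shifted_poisson", min = 2, mean = m)` (default, mean
#'   ~7.90 so the expected measurement total matches the emulated cohort).
#' @param contamination `list(fraction = , sdlog = )`: share of
#'   repeat-measured individuals whose draws are multiplied by a persistent
#'   elevation factor 1 + Lognormal(0, sdlog) (always > 1, median factor 2).
#'   Default fraction 0.2, sdlog 0.5.
#' @param p_kidney_dx_single Probability a single-measurement individual
#'   carries the kidney/urinary diagnosis flag; default 0.021.
#' @param age_law `"weighted"` (default) samples strata proportional to
#'   `group_params$n`, reproducing realistic stratum sizes and the ~55%
#'   male share; `"uniform"` samples draw ages uniformly over the age window
#'   with equal sexes.
#' @param study_window Two dates bounding first-draw dates; default
#'   2011-05-01 to 2018-01-31.
#' @param seed Integer RNG seed; identical configs yield identical cohorts.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_individuals = 44197L,
                                    group_params = default_group_params(),
                                    p_multi = 1 - 28595 / 44197,
                                    repeat_count_law = list(type = "shifted_poisson",
                                                            min = 2L,
                                                            mean = (151859 - 28595) / (44197 - 28595)),
                                    contamination = list(fraction = 0.2, sdlog = 0.5),
                                    p_kidney_dx_single = 0.021,
                                    age_law = c("weighted", "uniform"),
                                    study_window = as.Date(c("2011-05-01", "2018-01-31")),
                                    seed = 1L) {
  age_law <- match.arg(age_law)
  probs <- c(p_multi, contamination$fraction, p_kidney_dx_single)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "creatref_config_error")
  }
  required <- c("label", "sex", "age_min_days", "age_max_days", "n", "mean", "sd")
  if (!all(required %in% names(group_params))) {
    abort("`group_params` lacks required columns.", class = "creatref_config_error")
  }
  if (any(group_params$sd <= 0) || any(group_params$mean <= 0)) {
    abort("True means and SDs must be positive.", class = "creatref_config_error")
  }
  missing <- dplyr::anti_join(default_groups(), group_params, by = c("label", "sex"))
  if (nrow(missing)) {
    abort(sprintf("`group_params` misses %d default stratum(s), e.g. %s %s.",
                  nrow(missing), missing$label[1], missing$sex[1]),
          class = "creatref_config_error")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      group_params = group_params,
      p_multi = p_multi,
      repeat_count_law = repeat_count_law,
      contamination = contamination,
      p_kidney_dx_single = p_kidney_dx_single,
      age_law = age_law,
      study_window = as.Date(study_window),
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort_config"
  )
}

# draw per-individual measurement counts for repeat-measured individuals
.draw_repeat_counts <- function(law, n) {
  switch(law$type,
    constant = rep(as.integer(law$count), n),
    shifted_poisson = law$min + rpois(n, law$mean - law$min),
    abort(sprintf("Unknown repeat_count_law type '%s'.", law$type),
          class = "creatref_config_error")
  )
}

# truncated-positive normal draws: resample below `floor`, clamp as last resort
.rnorm_trunc <- function(mu, sigma, floor = 0.01) {
  v <- rnorm(length(mu), mu, sigma)
  for (i in 1:50) {
    bad <- v < floor
    if (!any(bad)) break
    v[bad] <- rnorm(sum(bad), mu[bad], sigma[bad])
  }
  pmax(v, floor)
}

#' Generate a synthetic measurement cohort
#'
#' Deterministic given the config seed. Each individual receives a sex and
#' age (hence birth date, back-computed from a draw date uniform over the
#' study window) and 1 or >= 2 draws. Healthy draws sample the
#' truncated-positive normal of the individual's age/sex stratum at the draw
#' date; repeat draws are spaced days to weeks apart and share the
#' individual's elevation state; contaminated draws are multiplied by the
#' individual's elevation factor (> 1). Single-measurement individuals carry
#' the diagnosis flag with probability `p_kidney_dx_single`, independent of
#' their value; repeat-measured individuals carry it iff contaminated.
#'
#' @param config A [synthetic_cohort_config()].
#' @return Measurement tibble: `individual_id`, `sex`, `birth_date`,
#'   `draw_date`, `creatinine` (mg/dL, 2 decimals), `kidney_dx`.
#' @export
#' @examples
#' cfg <- synthetic_cohort_config(n_individuals = 50, seed = 7)
#' generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  gp <- config$group_params
  n <- config$n_individuals
  w <- if (config$age_law == "weighted") gp$n else gp$age_max_days - gp$age_min_days
  gidx <- sample.int(nrow(gp), n, replace = TRUE, prob = w)

  # integer-day age uniform within the assigned stratum window
  lo <- ceiling(gp$age_min_days[gidx])
  hi <- ceiling(gp$age_max_days[gidx]) - 1L
  age0 <- lo + floor(runif(n) * (hi - lo + 1))

  window_days <- as.integer(config$study_window[2] - config$study_window[1])
  draw0 <- config$study_window[1] + floor(runif(n) * (window_days + 1))
  birth <- draw0 - age0

  is_multi <- runif(n) < config$p_multi
  counts <- rep(1L, n)
  counts[is_multi] <- .draw_repeat_counts(config$repeat_count_law, sum(is_multi))

  contaminated <- is_multi & runif(n) < config$contamination$fraction
  factor <- rep(1, n)
  factor[contaminated] <- 1 + rlnorm(sum(contaminated), 0, config$contamination$sdlog)

  kidney <- logical(n)
  kidney[!is_multi] <- runif(sum(!is_multi)) < config$p_kidney_dx_single
  kidney[is_multi] <- contaminated[is_multi]

  # expand individuals to draws; follow-up gaps of days to weeks
  idx <- rep.int(seq_len(n), counts)
  m <- length(idx)
  gaps <- 2L + rpois(m, 12)
  first <- !duplicated(idx)
  gaps[first] <- 0L
  offset <- as.integer(unlist(lapply(split(gaps, idx), cumsum), use.names = FALSE))
  # split() reorders by factor level; idx is already sorted so order is kept
  age_at <- age0[idx] + offset

  # stratum parameters at each draw's age; ages past the last bin reuse its
  # parameters (such records exist in an EHR and are filtered downstream)
  sexes <- gp$sex[gidx][idx]
  mu <- numeric(m)
  sigma <- numeric(m)
  for (s in c("M", "F")) {
    g <- gp[gp$sex == s, ]
    g <- g[order(g$age_min_days), ]
    sel <- which(sexes == s)
    bin <- findInterval(age_at[sel], g$age_min_days)
    bin <- pmin(pmax(bin, 1L), nrow(g))
    mu[sel] <- g$mean[bin]
    sigma[sel] <- g$sd[bin]
  }

  value <- .rnorm_trunc(mu, sigma) * factor[idx]

  tibble::tibble(
    individual_id = sprintf("S%06d", idx),
    sex = sexes,
    birth_date = birth[idx],
    draw_date = draw0[idx] + offset,
    creatinine = round_limit(value, 2),
    kidney_dx = kidney[idx]
  )
}

#' True reference limits of a synthetic stratum
#'
#' The generator's ground truth for parameter-recovery tests: true mean
#' +/- 1.96 * true SD, unrounded.
#'
#' @param config A [synthetic_cohort_config()].
#' @param label Stratum label, e.g. `"14-15 years"`.
#' @param sex `"M"` or `"F"`.
#' @return Named numeric vector `c(lower = , upper = )` in mg/dL.
#' @export
#' @examples
#' cfg <- synthetic_cohort_config()
#' true_limits(cfg, "Infant (1-12 months)", "F")  # 0.1128 0.3872
true_limits <- function(config, label, sex) {
  gp <- config$group_params
  row <- gp[gp$label == label & gp$sex == sex, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown stratum: %s %s", label, sex),
          class = "creatref_lookup_error")
  }
  c(lower = row$mean - 1.96 * row$sd, upper = row$mean + 1.96 * row$sd)
}
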