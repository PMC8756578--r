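# brute-force sort-and-interpolate quantile oracle: h = (n-1)p + 1 on the
# sorted sample, linear between adjacent order statistics
bf_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# compare reported (2-decimal) concentrations in integer cents to dodge
# binary floating-point noise in differences like 0.61 - 0.63
cents <- function(x, decimals = 2) {
  as.integer(round(round_limit(x, decimals) * 10^decimals))
}

make_records <- function(id, sex = "M", birth = "2010-01-01",
                         draw = "2012-01-01", creatinine = 0.4,
                         kidney = FALSE) {
  tibble::tibble(
    individual_id = id, sex = sex,
    birth_date = as.Date(birth), draw_date = as.Date(draw),
    creatinine = creatinine, kidney_dx = kidney
  )
}

# external-study URL series used as monotonicity fixtures: age-ordered upper
# reference limits with the positions where the series reverts (drops below
# the preceding age bin)
external_url_series <- function() {
  list(
    uemura_f = list(
      labels = c("1-2 years", "2-3 years", "3-4 years", "4-5 years",
                 "5-6 years", "6-7 years", "7-8 years", "8-9 years",
                 "9-10 years", "10-11 years", "11-12 years", "12-13 years",
                 "13-14 years", "14-15 years", "15-16 years", "16-17 years"),
      urls = c(0.32, 0.37, 0.37, 0.40, 0.45, 0.48, 0.49, 0.53,
               0.50, 0.57, 0.58, 0.61, 0.69, 0.71, 0.72, 0.74),
      marked = "9-10 years"
    ),
    uemura_m = list(
      labels = c("13-14 years", "14-15 years", "15-16 years", "16-17 years"),
      urls = c(0.80, 0.96, 0.93, 0.96),
      marked = "15-16 years"
    ),
    pottel_f = list(
      labels = c("13-14 years", "14-15 years", "15-16 years",
                 "16-17 years", "17-18 years"),
      urls = c(0.83, 0.78, 0.92, 0.95, 0.94),
      marked = c("14-15 years", "17-18 years")
    )
  )
}

# small clean cohort configs used across tests
clean_config <- function(n = 27911, seed = 1, ...) {
  synthetic_cohort_config(
    n_individuals = n, p_multi = 0,
    contamination = list(fraction = 0, sdlog = 0.5),
    seed = seed, ...
  )
}
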