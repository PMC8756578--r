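#' Bundled pediatric serum creatinine reference values
#'
#' Per-stratum summary statistics for serum creatinine (compensated Jaffe,
#' mg/dL) in a large East Asian tertiary-care pediatric cohort: 27,911
#' single-measurement individuals aged 1 month to below 18 years, split into
#' 36 age/sex strata. These values serve two roles: they are the default true
#' group parameters of the synthetic cohort generator (so a default synthetic
#' run reproduces a realistic reference table end to end), and they are the
#' worked-example fixture for the desk-arithmetic operations
#' ([parametric_limits()], [sex_url_differences()], [detect_reversions()]).
#'
#' `p2_5` / `p97_5` are the reported two-decimal reference limits; `mean` and
#' `sd` are the reported two-decimal group mean and standard deviation after
#' single-measurement selection and upper-fence trimming.
#'
#' @return A tibble with one row per stratum: `label`, `sex` (`"M"`/`"F"`),
#'   `age_min_days`, `age_max_days`, `n`, `mean`, `sd`, `p2_5`, `p97_5`.
#' @export
#' @examples
#' default_group_params()
default_group_params <- function() {
  groups <- default_groups()
  stats <- tibble::tribble(
    ~label,                 ~sex, ~n,    ~mean, ~sd,   ~p2_5, ~p97_5,
    "Infant (1-12 months)", "M",  2227L, 0.26,  0.07,  0.12,  0.39,
    "Infant (1-12 months)", "F",  1527L, 0.25,  0.07,  0.11,  0.39,
    "1-2 years",            "M",  1653L, 0.29,  0.07,  0.15,  0.42,
    "1-2 years",            "F",  1367L, 0.29,  0.07,  0.15,  0.42,
    "2-3 years",            "M",  1230L, 0.33,  0.07,  0.19,  0.46,
    "2-3 years",            "F",  1012L, 0.31,  0.07,  0.17,  0.45,
    "3-4 years",            "M",  1011L, 0.35,  0.07,  0.21,  0.49,
    "3-4 years",            "F",   824L, 0.34,  0.07,  0.20,  0.48,
    "4-5 years",            "M",   946L, 0.37,  0.07,  0.23,  0.51,
    "4-5 years",            "F",   708L, 0.37,  0.07,  0.23,  0.50,
    "5-6 years",            "M",   842L, 0.39,  0.07,  0.25,  0.53,
    "5-6 years",            "F",   662L, 0.38,  0.07,  0.24,  0.52,
    "6-7 years",            "M",   723L, 0.42,  0.08,  0.26,  0.57,
    "6-7 years",            "F",   565L, 0.41,  0.08,  0.25,  0.56,
    "7-8 years",            "M",   602L, 0.44,  0.08,  0.28,  0.59,
    "7-8 years",            "F",   495L, 0.44,  0.08,  0.28,  0.60,
    "8-9 years",            "M",   559L, 0.46,  0.08,  0.30,  0.61,
    "8-9 years",            "F",   454L, 0.46,  0.08,  0.30,  0.61,
    "9-10 years",           "M",   519L, 0.49,  0.08,  0.33,  0.63,
    "9-10 years",           "F",   452L, 0.47,  0.08,  0.31,  0.62,
    "10-11 years",          "M",   491L, 0.52,  0.08,  0.36,  0.68,
    "10-11 years",          "F",   371L, 0.49,  0.07,  0.35,  0.63,
    "11-12 years",          "M",   496L, 0.54,  0.09,  0.36,  0.71,
    "11-12 years",          "F",   381L, 0.51,  0.09,  0.33,  0.70,
    "12-13 years",          "M",   517L, 0.58,  0.10,  0.38,  0.78,
    "12-13 years",          "F",   399L, 0.54,  0.09,  0.36,  0.73,
    "13-14 years",          "M",   487L, 0.64,  0.11,  0.42,  0.85,
    "13-14 years",          "F",   397L, 0.58,  0.08,  0.42,  0.74,
    "14-15 years",          "M",   465L, 0.72,  0.11,  0.50,  0.94,
    "14-15 years",          "F",   419L, 0.61,  0.09,  0.43,  0.79,
    "15-16 years",          "M",   619L, 0.79,  0.12,  0.55,  1.02,
    "15-16 years",          "F",   550L, 0.62,  0.10,  0.42,  0.81,
    "16-17 years",          "M",   726L, 0.82,  0.12,  0.58,  1.05,
    "16-17 years",          "F",   708L, 0.63,  0.09,  0.45,  0.82,
    "17-18 years",          "M",  1278L, 0.84,  0.11,  0.62,  1.05,
    "17-18 years",          "F",  1229L, 0.64,  0.09,  0.46,  0.82
  )
  out <- dplyr::left_join(groups, stats, by = c("label", "sex"))
  stopifnot(!anyNA(out$mean))
  out
}
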