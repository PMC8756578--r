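#' Age at blood draw in whole days
#'
#' Exact calendar-day difference between birth and draw date; no fractional
#' days, no average-month approximations.
#'
#' @param birth_date,draw_date Date vectors (or anything `as.Date()` accepts),
#'   recycled to a common length.
#' @return Integer vector of whole days.
#' @export
#' @examples
#' age_at_draw("2010-01-01", "2010-01-31")
age_at_draw <- function(birth_date, draw_date) {
  birth_date <- as.Date(birth_date)
  draw_date <- as.Date(draw_date)
  age <- as.integer(draw_date - birth_date)
  if (anyNA(age)) {
    abort("Unparseable birth or draw date.", class = "creatref_validation_error")
  }
  if (any(age < 0)) {
    bad <- which(age < 0)
    abort(
      sprintf("Draw before birth at position(s): %s", paste(bad, collapse = ", ")),
      class = "creatref_validation_error"
    )
  }
  age
}

#' Default age/sex stratification
#'
#' The 36 analysis strata: per sex, one infant bin from 1 month up to the
#' first-birthday bin edge, then seventeen 1-year bins. All windows are
#' half-open `[age_min_days, age_max_days)`; yearly edges sit at 365.25-day
#' multiples so the bins tile `[30 days, 18 years)` with no gaps or overlaps.
#'
#' @param age_lower_days Inclusive lower bound of the infant bin (default 30).
#' @param age_upper_years Exclusive overall upper bound in years (default 18).
#' @return A tibble: `label`, `sex`, `age_min_days`, `age_max_days`, ordered
#'   by ascending age with males before females within each age bin.
#' @export
#' @examples
#' nrow(default_groups())  # 36
default_groups <- function(age_lower_days = 30, age_upper_years = 18) {
  year <- 365.25
  k <- seq_len(age_upper_years - 1)
  bins <- tibble::tibble(
    label = c(
      "Infant (1-12 months)",
      sprintf("%d-%d years", k, k + 1)
    ),
    age_min_days = c(age_lower_days, k * year),
    age_max_days = c(year, pmin((k + 1) * year, age_upper_years * year))
  )
  out <- tidyr::crossing(bins, sex = c("M", "F"))
  out <- dplyr::arrange(out, .data$age_min_days, dplyr::desc(.data$sex))
  dplyr::select(out, "label", "sex", "age_min_days", "age_max_days")
}

# validate that `groups` is a proper half-open tiling per sex; abort on overlap
.check_group_tiling <- function(groups) {
  for (s in unique(groups$sex)) {
    g <- groups[groups$sex == s, ]
    g <- g[order(g$age_min_days), ]
    if (any(g$age_min_days >= g$age_max_days)) {
      abort("Group with empty age window.", class = "creatref_integrity_error")
    }
    if (nrow(g) > 1 && any(g$age_min_days[-1] < g$age_max_days[-nrow(g)])) {
      abort("Overlapping age windows within one sex.", class = "creatref_integrity_error")
    }
  }
  invisible(groups)
}

#' Assign records to age/sex strata
#'
#' Finds, for each (age, sex) pair, the unique stratum whose half-open window
#' contains the age. Ages below the youngest window (neonates) or at/above the
#' oldest bound get `NA`.
#'
#' @param age_days Numeric vector of ages in days (fractional allowed).
#' @param sex Character vector of `"M"`/`"F"`, recycled against `age_days`.
#' @param groups Stratum table as from [default_groups()].
#' @return Character vector of stratum labels (`NA` where no stratum applies).
#' @export
#' @examples
#' assign_group(180, "M")
#' assign_group(20, "F")  # neonate -> NA
assign_group <- function(age_days, sex, groups = default_groups()) {
  .check_group_tiling(groups)
  n <- max(length(age_days), length(sex))
  age_days <- rep_len(age_days, n)
  sex <- rep_len(sex, n)
  out <- rep(NA_character_, n)
  for (s in unique(groups$sex)) {
    g <- groups[groups$sex == s, ]
    g <- g[order(g$age_min_days), ]
    sel <- which(sex == s)
    if (!length(sel)) next
    idx <- findInterval(age_days[sel], g$age_min_days)
    ok <- idx >= 1 & age_days[sel] < g$age_max_days[pmax(idx, 1)]
    # a gap in a non-default tiling leaves idx pointing at the previous bin;
    # the age_max_days check above rejects those
    out[sel[ok]] <- g$label[idx[ok]]
  }
  out
}

#' Keep only individuals measured exactly once
#'
#' The indirect-sampling exclusion step: individuals with repeated creatinine
#' measurements are presumed to be under renal follow-up (AKI/CKD risk) and
#' are dropped wholesale; an individual survives iff it has exactly one
#' measurement.
#'
#' @param records Measurement tibble with at least `individual_id`.
#' @param collapse_same_day Collapse duplicate (individual, draw_date) rows to
#'   the first before counting multiplicity.
#' @return A list: `records` (the kept single measurements, input order
#'   preserved) and `n_excluded_individuals`.
#' @export
select_single_measurement <- function(records, collapse_same_day = FALSE) {
  if (collapse_same_day && nrow(records)) {
    records <- dplyr::distinct(records, .data$individual_id, .data$draw_date,
                               .keep_all = TRUE)
  }
  counts <- dplyr::count(records, .data$individual_id)
  singles <- counts$individual_id[counts$n == 1L]
  list(
    records = records[records$individual_id %in% singles, , drop = FALSE],
    n_excluded_individuals = sum(counts$n > 1L)
  )
}

#' Enrollment flow summary
#'
#' Stage-by-stage accounting of the cohort build, mirroring an enrollment
#' flowchart: retrieved measurements and individuals, single-measurement
#' survivors, fence-removed outliers, and the final population by sex.
#' Outlier and final counts are `NA` until the estimation stage completes
#' them.
#'
#' @param n_measurements_retrieved,n_individuals_retrieved,n_single_measurement
#'   Retrieval-stage counts.
#' @param n_outliers_removed,n_final,n_final_male,n_final_female
#'   Estimation-stage counts.
#' @return A `flow_summary` list.
#' @export
flow_summary <- function(n_measurements_retrieved = 0L,
                         n_individuals_retrieved = 0L,
                         n_single_measurement = 0L,
                         n_outliers_removed = NA_integer_,
                         n_final = NA_integer_,
                         n_final_male = NA_integer_,
                         n_final_female = NA_integer_) {
  structure(
    list(
      n_measurements_retrieved = as.integer(n_measurements_retrieved),
      n_individuals_retrieved = as.integer(n_individuals_retrieved),
      n_single_measurement = as.integer(n_single_measurement),
      n_outliers_removed = as.integer(n_outliers_removed),
      n_final = as.integer(n_final),
      n_final_male = as.integer(n_final_male),
      n_final_female = as.integer(n_final_female)
    ),
    class = "flow_summary"
  )
}

.validate_flow <- function(flow) {
  with(flow, {
    if (anyNA(c(n_outliers_removed, n_final, n_final_male, n_final_female))) {
      abort("Flow summary is incomplete.", class = "creatref_integrity_error")
    }
    if (n_final != n_single_measurement - n_outliers_removed ||
        n_final != n_final_male + n_final_female) {
      abort("Flow summary counts are inconsistent.", class = "creatref_integrity_error")
    }
  })
  invisible(flow)
}

#' Build the stratified cohort
#'
#' Applies, in order: age-window (and optional study-window) eligibility,
#' single-measurement selection, and stratum assignment. Every kept record
#' lands in exactly one stratum.
#'
#' @param records Validated measurement tibble (see [read_measurements()]).
#' @param groups Stratum table, default [default_groups()].
#' @param config A [pipeline_config()].
#' @return A `creat_cohort` list: `groups` (the stratum table with a `values`
#'   list-column of creatinine vectors), `records` (kept records with
#'   `age_days` and `label`), and `flow` (a partially filled [flow_summary()]).
#' @export
build_cohort <- function(records, groups = default_groups(),
                         config = pipeline_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) && !all(records$sex %in% unique(groups$sex))) {
    bad <- unique(records$sex[!records$sex %in% unique(groups$sex)])
    abort(sprintf("Unmappable sex code(s): %s", paste(bad, collapse = ", ")),
          class = "creatref_validation_error")
  }
  .check_group_tiling(groups)

  n_meas <- nrow(records)
  n_indiv <- dplyr::n_distinct(records$individual_id)

  if (n_meas) {
    records$age_days <- age_at_draw(records$birth_date, records$draw_date)
  } else {
    records$age_days <- integer(0)
  }

  if (config$multiplicity_scope == "all") {
    sel_all <- select_single_measurement(records, config$collapse_same_day)
    records <- sel_all$records
  }

  lo <- config$age_lower_days
  hi <- config$age_upper_years * 365.25
  eligible <- records[records$age_days >= lo & records$age_days < hi, , drop = FALSE]
  if (!is.null(config$study_window) && nrow(eligible)) {
    eligible <- eligible[eligible$draw_date >= config$study_window[1] &
                           eligible$draw_date <= config$study_window[2], , drop = FALSE]
  }

  if (config$multiplicity_scope == "eligible") {
    sel <- select_single_measurement(eligible, config$collapse_same_day)
  } else {
    sel <- list(records = eligible, n_excluded_individuals = sel_all$n_excluded_individuals)
  }
  kept <- sel$records
  kept$label <- assign_group(kept$age_days, kept$sex, groups)
  stopifnot(!anyNA(kept$label))

  key <- paste(kept$label, kept$sex, sep = "\r")
  vals <- split(kept$creatinine, factor(key, levels = paste(groups$label, groups$sex, sep = "\r")))
  out_groups <- groups
  out_groups$values <- unname(vals)

  structure(
    list(
      groups = out_groups,
      records = kept,
      flow = flow_summary(
        n_measurements_retrieved = n_meas,
        n_individuals_retrieved = n_indiv,
        n_single_measurement = nrow(kept)
      )
    ),
    class = "creat_cohort"
  )
}
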