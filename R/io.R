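#' Read measurement records from CSV
#'
#' Reads a headered UTF-8 CSV of laboratory measurement rows into validated
#' records. EHR exports vary, so `column_map` renames arbitrary headers onto
#' the canonical schema: `individual_id`, `sex` (M/F), `birth_date`
#' (ISO-8601), `draw_date`, `creatinine` (mg/dL), optional `kidney_dx`
#' (logical) and `age_days`. Either `birth_date` or `age_days` must be
#' present; when both are, `birth_date` wins and a note is emitted.
#'
#' Rows violating the record invariants (creatinine not a positive finite
#' number, unparseable or reversed dates, unknown sex code) are rejected and
#' reported with their row numbers rather than aborting the read — EHR
#' extracts are dirty, and silent drops would make the enrollment accounting
#' unauditable. `strict = TRUE` turns any rejection into an error.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's headers, e.g. `c(individual_id = "PID", sex = "GENDER")`.
#' @param strict Abort on any invalid row instead of rejecting it.
#' @return A tibble of valid records in input order (`individual_id`, `sex`,
#'   `birth_date`, `draw_date`, `creatinine`, `kidney_dx`), with attribute
#'   `"rejected"`: a tibble of `row` numbers and `reason`s.
#' @export
read_measurements <- function(path, column_map = NULL, strict = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path), class = "creatref_config_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(column_map)) {
    present <- column_map[column_map %in% names(raw)]
    absent <- setdiff(column_map, names(raw))
    if (length(absent)) {
      abort(sprintf("Mapped column(s) missing from file: %s",
                    paste(absent, collapse = ", ")),
            class = "creatref_config_error")
    }
    names(raw)[match(present, names(raw))] <- names(present)
  }
  needed <- c("individual_id", "sex", "draw_date", "creatinine")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("Required column(s) missing: %s", paste(missing, collapse = ", ")),
          class = "creatref_config_error")
  }
  has_birth <- "birth_date" %in% names(raw)
  has_age <- "age_days" %in% names(raw)
  if (!has_birth && !has_age) {
    abort("Need either a `birth_date` or an `age_days` column.",
          class = "creatref_config_error")
  }
  if (has_birth && has_age) {
    inform("Both `birth_date` and `age_days` present; using `birth_date`.")
  }

  n <- nrow(raw)
  draw <- as.Date(suppressWarnings(readr::parse_date(raw$draw_date)))
  if (has_birth) {
    birth <- as.Date(suppressWarnings(readr::parse_date(raw$birth_date)))
  } else {
    age <- suppressWarnings(as.numeric(raw$age_days))
    birth <- draw - age
  }
  creat <- suppressWarnings(as.numeric(raw$creatinine))
  kidney <- if ("kidney_dx" %in% names(raw)) {
    toupper(trimws(raw$kidney_dx)) %in% c("TRUE", "T", "1", "YES")
  } else {
    rep(FALSE, n)
  }
  sex <- toupper(trimws(raw$sex))

  reasons <- vector("list", n)
  flag <- function(bad, why) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  flag(is.na(draw), "unparseable draw_date")
  flag(is.na(birth), if (has_birth) "unparseable birth_date" else "unparseable age_days")
  flag(!is.na(creat) & (!is.finite(creat) | creat <= 0), "creatinine not a positive finite number")
  flag(is.na(creat), "unparseable creatinine")
  flag(!sex %in% c("M", "F"), "sex not one of M/F")
  flag(!is.na(draw) & !is.na(birth) & draw < birth, "draw_date before birth_date")

  bad <- lengths(reasons) > 0
  rejected <- tibble::tibble(
    row = which(bad),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; ")
  )
  if (nrow(rejected) && strict) {
    abort(
      c("Invalid measurement rows:",
        setNames(sprintf("row %d: %s", head(rejected$row, 10),
                         head(rejected$reason, 10)), rep("x", min(10, nrow(rejected))))),
      class = "creatref_validation_error"
    )
  }
  if (nrow(rejected)) {
    warn(sprintf("Rejected %d invalid row(s); see attr(, 'rejected').", nrow(rejected)))
  }

  out <- tibble::tibble(
    individual_id = raw$individual_id[!bad],
    sex = sex[!bad],
    birth_date = birth[!bad],
    draw_date = draw[!bad],
    creatinine = creat[!bad],
    kidney_dx = kidney[!bad]
  )
  attr(out, "rejected") <- rejected
  out
}

#' Write measurement records to CSV
#'
#' Companion writer to [read_measurements()]: ISO-8601 dates, headered UTF-8
#' CSV. Reading the written file back yields an identical record collection.
#'
#' @param records Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  cols <- c("individual_id", "sex", "birth_date", "draw_date", "creatinine", "kidney_dx")
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write the reference-interval table
#'
#' Publication-shaped CSV: one row per stratum, ordered by ascending age with
#' males before females, values rounded to reporting precision. The written
#' P2.5/P97.5 are the parametric limits (the default display; empirical
#' percentiles remain available on the estimates tibble).
#'
#' @param estimates Estimates tibble from [estimate_all()].
#' @param path Output path.
#' @param config A [pipeline_config()] supplying `rounding_decimals`.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(estimates, path, config = pipeline_config()) {
  if (anyDuplicated(estimates[, c("label", "sex")])) {
    abort("Duplicate (group, sex) rows in estimates.", class = "creatref_integrity_error")
  }
  d <- config$rounding_decimals
  out <- estimates |>
    dplyr::arrange(.data$age_min_days, dplyr::desc(.data$sex)) |>
    dplyr::transmute(
      group = .data$label,
      sex = .data$sex,
      n = .data$n,
      mean = round_limit(.data$mean, d),
      sd = round_limit(.data$sd, d),
      p2_5 = round_limit(.data$p2_5_param, d),
      p97_5 = round_limit(.data$p97_5_param, d),
      outliers_removed = .data$n_outliers_removed,
      meets_min_n = .data$meets_min_n
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
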