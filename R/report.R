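#' Render the enrollment flow summary as text
#'
#' Human-readable four-stage account of the cohort build: retrieved
#' measurements/individuals, single-measurement survivors, fence-removed
#' outliers (with their percentage of the post-exclusion count, one decimal),
#' and the final population by sex.
#'
#' @param flow A completed [flow_summary()].
#' @return A single character string (newline-separated block).
#' @export
#' @examples
#' f <- flow_summary(151859, 44197, 28595, 684, 27911, 15391, 12520)
#' cat(render_flow_summary(f))
render_flow_summary <- function(flow) {
  .validate_flow(flow)
  fmt <- function(x) format(x, big.mark = ",", trim = TRUE, scientific = FALSE)
  pct <- if (flow$n_single_measurement > 0) {
    sprintf("%.1f%%", 100 * flow$n_outliers_removed / flow$n_single_measurement)
  } else {
    "0.0%"
  }
  paste(
    sprintf("Measurements retrieved:         %s (%s individuals)",
            fmt(flow$n_measurements_retrieved), fmt(flow$n_individuals_retrieved)),
    sprintf("Single-measurement individuals: %s", fmt(flow$n_single_measurement)),
    sprintf("Outliers removed (upper fence): %s (%s)",
            fmt(flow$n_outliers_removed), pct),
    sprintf("Final reference population:     %s (%s male / %s female)",
            fmt(flow$n_final), fmt(flow$n_final_male), fmt(flow$n_final_female)),
    sep = "\n"
  )
}

# parse the single YAML run configuration (pipeline / columns / synthetic)
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  take <- function(section, ctor) {
    args <- raw[[section]] %||% list()
    do.call(ctor, args[intersect(names(args), names(formals(ctor)))])
  }
  cols <- raw[["columns"]]
  list(
    pipeline = take("pipeline", pipeline_config),
    synthetic = take("synthetic", synthetic_cohort_config),
    column_map = if (length(cols)) unlist(cols) else NULL
  )
}

# write a tibble, returning path (possibly of an empty file with header only)
.write_output <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the full estimation pipeline on a measurement file
#'
#' End-to-end run: read and validate records, build the stratified cohort,
#' trim and estimate, and write the outputs into `out_dir`:
#' `reference_table.csv`, `flow_summary.csv`, `reversion_report.csv`,
#' `sensitivity.csv` (when any record carries a diagnosis flag), and
#' `manifest.json` (config snapshot, versions, checksums). The rendered flow
#' summary goes to stderr.
#'
#' @param input Measurement CSV path.
#' @param config_path Optional YAML run configuration (sections `pipeline`,
#'   `columns`, `synthetic`).
#' @param out_dir Output directory, created if needed.
#' @param strict Abort on any invalid input row.
#' @return Invisibly, a list with `status` (0), `flow`, `estimates`, and
#'   `files`.
#' @export
cmd_estimate <- function(input, config_path = NULL, out_dir, strict = FALSE) {
  rc <- read_run_config(config_path)
  config <- rc$pipeline

  records <- read_measurements(input, rc$column_map, strict = strict)
  if (!nrow(records)) {
    abort("estimate: no eligible records in input.", class = "creatref_validation_error")
  }
  cohort <- build_cohort(records, default_groups(config$age_lower_days,
                                                 config$age_upper_years), config)
  if (!nrow(cohort$records)) {
    abort("estimate: no eligible records after cohort filters.",
          class = "creatref_validation_error")
  }
  res <- estimate_all(cohort, config)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  d <- config$rounding_decimals
  files <- character(0)
  files["reference_table"] <-
    write_reference_table(res$estimates, file.path(out_dir, "reference_table.csv"), config)

  flow_tbl <- tibble::tibble(
    stage = names(unclass(res$flow)),
    count = unlist(unclass(res$flow))
  )
  files["flow_summary"] <- .write_output(flow_tbl, file.path(out_dir, "flow_summary.csv"))

  rev_tbl <- res$estimates |>
    dplyr::arrange(.data$sex, .data$age_min_days) |>
    dplyr::group_by(.data$sex) |>
    dplyr::reframe(label = detect_reversions(round_limit(.data$p97_5_param, d),
                                             .data$label))
  files["reversion_report"] <- .write_output(rev_tbl, file.path(out_dir, "reversion_report.csv"))

  if (any(records$kidney_dx)) {
    flagged <- unique(records$individual_id[records$kidney_dx])
    restricted <- records[!records$individual_id %in% flagged, , drop = FALSE]
    res_r <- estimate_all(build_cohort(restricted, cohort$groups[, 1:4], config), config)
    comp <- sensitivity_compare(res$estimates, res_r$estimates, d)
    files["sensitivity"] <- .write_output(comp$by_group, file.path(out_dir, "sensitivity.csv"))
  }

  manifest <- list(
    tool = "creatref",
    version = as.character(packageVersion("creatref")),
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    input = normalizePath(input),
    config = unclass(config),
    flow = unclass(res$flow),
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", Date = "ISO8601")
  files["manifest"] <- manifest_path

  message(render_flow_summary(res$flow))
  invisible(list(status = 0L, flow = res$flow, estimates = res$estimates, files = files))
}

#' Simulate a synthetic measurement file with known truth
#'
#' Generates a synthetic EHR cohort and writes it as a measurement CSV plus a
#' truth table of per-stratum true parameters and true reference limits
#' (`<out>_truth.csv`), for parameter-recovery exercises.
#'
#' @param config_path Optional YAML run configuration (its `synthetic`
#'   section).
#' @param seed Integer seed overriding the configured one.
#' @param out Output CSV path for the measurements.
#' @return Invisibly, a list with `status`, `records`, and `files`.
#' @export
cmd_simulate <- function(config_path = NULL, seed = NULL, out) {
  rc <- read_run_config(config_path)
  cfg <- rc$synthetic
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  records <- generate_cohort(cfg)
  write_measurements(records, out)
  truth <- cfg$group_params |>
    dplyr::transmute(
      label = .data$label, sex = .data$sex,
      true_mean = .data$mean, true_sd = .data$sd,
      true_lower = .data$mean - 1.96 * .data$sd,
      true_upper = .data$mean + 1.96 * .data$sd
    )
  truth_path <- sub("\\.csv$", "", out)
  truth_path <- paste0(truth_path, "_truth.csv")
  .write_output(truth, truth_path)
  invisible(list(status = 0L, records = records, files = c(measurements = out, truth = truth_path)))
}
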