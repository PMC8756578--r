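#' Pipeline configuration
#'
#' Bundles every tunable constant of the reference-interval pipeline. The
#' defaults reproduce the published analysis conditions: a one-sided Tukey
#' fence at Q3 + 1.5*IQR, parametric limits at mean +/- 1.96 SD, the IFCC
#' minimum of 120 reference individuals per partition, two-decimal reporting
#' (mg/dL laboratory resolution), and an eligibility window of 1 month
#' (30 days) to below 18 years of age.
#'
#' @param fence_multiplier Multiple of the IQR added to Q3 to form the upper
#'   outlier fence. Dimensionless, must be > 0. Default 1.5 (Tukey's value).
#' @param z_value Normal multiplier for the parametric central-95% limits.
#'   Default 1.96 (the conventional constant, not the exact quantile).
#' @param min_group_n Minimum stratum size for the adequacy flag; default 120,
#'   the IFCC recommendation for establishing reference values.
#' @param rounding_decimals Decimals used when reporting concentrations;
#'   default 2 (0.01 mg/dL resolution).
#' @param quantile_method Quantile interpolation rule: `"linear"`
#'   (spreadsheet-style linear interpolation at h = (n-1)p, the default),
#'   `"hinges"` (Tukey hinge style), or `"nearest"`.
#' @param age_lower_days Inclusive lower eligibility bound in whole days;
#'   default 30 ("1 month"; neonates below it are excluded).
#' @param age_upper_years Exclusive upper eligibility bound in years;
#'   default 18.
#' @param study_window Optional length-2 Date vector; draws outside it are
#'   dropped at retrieval. `NULL` (default) keeps all dates.
#' @param outlier_floor_n Groups smaller than this are flagged and left
#'   untrimmed rather than fenced; default 4 (a fence from fewer points is
#'   meaningless).
#' @param collapse_same_day If `TRUE`, duplicate draws of one individual on
#'   one calendar day are collapsed to the first before multiplicity is
#'   counted. Default `FALSE`: repeat same-day draws signal monitoring and
#'   count as multiple measurements.
#' @param multiplicity_scope Whether measurement multiplicity is counted over
#'   `"eligible"` records only (after the age/window filter, the default) or
#'   over `"all"` retrieved records.
#'
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$fence_multiplier
pipeline_config <- function(fence_multiplier = 1.5,
                            z_value = 1.96,
                            min_group_n = 120L,
                            rounding_decimals = 2L,
                            quantile_method = c("linear", "hinges", "nearest"),
                            age_lower_days = 30,
                            age_upper_years = 18,
                            study_window = NULL,
                            outlier_floor_n = 4L,
                            collapse_same_day = FALSE,
                            multiplicity_scope = c("eligible", "all")) {
  quantile_method <- match.arg(quantile_method)
  multiplicity_scope <- match.arg(multiplicity_scope)
  if (!is.numeric(fence_multiplier) || fence_multiplier <= 0) {
    abort("`fence_multiplier` must be a positive number.", class = "creatref_config_error")
  }
  if (!is.numeric(z_value) || z_value <= 0) {
    abort("`z_value` must be a positive number.", class = "creatref_config_error")
  }
  if (!is.numeric(rounding_decimals) || rounding_decimals < 0) {
    abort("`rounding_decimals` must be >= 0.", class = "creatref_config_error")
  }
  if (!is.numeric(age_lower_days) || !is.numeric(age_upper_years) ||
      age_lower_days < 0 || age_lower_days >= age_upper_years * 365.25) {
    abort("`age_lower_days` must fall below `age_upper_years` expressed in days.",
          class = "creatref_config_error")
  }
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    if (length(study_window) != 2L || any(is.na(study_window)) ||
        study_window[1] > study_window[2]) {
      abort("`study_window` must be two ordered dates.", class = "creatref_config_error")
    }
  }
  structure(
    list(
      fence_multiplier = fence_multiplier,
      z_value = z_value,
      min_group_n = as.integer(min_group_n),
      rounding_decimals = as.integer(rounding_decimals),
      quantile_method = quantile_method,
      age_lower_days = age_lower_days,
      age_upper_years = age_upper_years,
      study_window = study_window,
      outlier_floor_n = as.integer(outlier_floor_n),
      collapse_same_day = isTRUE(collapse_same_day),
      multiplicity_scope = multiplicity_scope
    ),
    class = "pipeline_config"
  )
}
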