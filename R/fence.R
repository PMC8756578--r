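#' First and third quartiles
#'
#' Order-statistic quartiles of a value vector under a selectable
#' interpolation rule. `"linear"` interpolates at h = (n-1)p, the
#' spreadsheet-default rule; `"hinges"` averages at discontinuities (Tukey
#' hinge style); `"nearest"` takes the nearest order statistic.
#'
#' @param values Numeric vector, at least one finite value.
#' @param method Interpolation rule.
#' @return Named numeric vector `c(q1 = , q3 = )`.
#' @export
#' @examples
#' quartiles(c(1, 2, 3, 4))  # 1.75, 3.25
quartiles <- function(values, method = c("linear", "hinges", "nearest")) {
  type <- .match_quantile_method(method)
  if (!length(values) || !all(is.finite(values))) {
    abort("`values` must be non-empty and finite.", class = "creatref_domain_error")
  }
  q <- quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' One-sided Tukey upper-fence trimming
#'
#' Removes values strictly above Q3 + `fence_multiplier` * IQR in a single
#' pass: the fence is computed once on the input and not recomputed after
#' removal. Only the upper side is trimmed — in an indirect reference cohort,
#' residual pathology inflates creatinine; low values are retained by design.
#' Groups below `floor_n` are flagged and returned untrimmed.
#'
#' @param values Numeric vector of concentrations (mg/dL).
#' @param fence_multiplier IQR multiple, > 0; default 1.5.
#' @param method Quartile interpolation rule, see [quartiles()].
#' @param floor_n Minimum group size for trimming; default 4.
#' @return A `fence_result` list: `q1`, `q3`, `iqr`, `upper_fence`, `kept`,
#'   `removed`, `n_removed`, `flagged`.
#' @export
#' @examples
#' remove_upper_outliers(c(0.2, 0.3, 0.3, 0.4, 1.0))  # fence 0.55, removes 1.0
remove_upper_outliers <- function(values, fence_multiplier = 1.5,
                                  method = c("linear", "hinges", "nearest"),
                                  floor_n = 4L) {
  method <- match.arg(method)
  if (!is.numeric(fence_multiplier) || fence_multiplier <= 0) {
    abort("`fence_multiplier` must be > 0.", class = "creatref_domain_error")
  }
  if (length(values) < floor_n) {
    return(structure(
      list(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_, upper_fence = NA_real_,
           kept = values, removed = numeric(0), n_removed = 0L, flagged = TRUE),
      class = "fence_result"
    ))
  }
  q <- quartiles(values, method)
  iqr <- q[["q3"]] - q[["q1"]]
  fence <- q[["q3"]] + fence_multiplier * iqr
  above <- values > fence
  res <- structure(
    list(q1 = q[["q1"]], q3 = q[["q3"]], iqr = iqr, upper_fence = fence,
         kept = values[!above], removed = values[above],
         n_removed = sum(above), flagged = FALSE),
    class = "fence_result"
  )
  stopifnot(
    res$iqr >= 0,
    all(res$kept <= res$upper_fence),
    all(res$removed > res$upper_fence),
    length(res$kept) + res$n_removed == length(values)
  )
  res
}
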