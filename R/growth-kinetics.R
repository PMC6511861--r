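#' Estimate an exponential growth rate from one OD600 time series
#'
#' Restricts the curve to the exponential window (OD600 in `od_window`,
#' endpoints inclusive) and fits natural-log OD600 against time by ordinary
#' least squares; the slope is the growth rate lambda (1/h). On a noiseless
#' exponential the estimate is exact; the fit is reported with its standard
#' error and r-squared. Slightly negative slopes are reported as-is (with a
#' warning) rather than truncated at zero, so that downstream averages stay
#' unbiased.
#'
#' @param data A data frame with numeric columns `time_h` and `od600`
#'   (one culture).
#' @param od_window Length-2 numeric, the OD600 range used for fitting;
#'   default `c(0.1, 0.5)`.
#' @return A one-row tibble: `lambda_per_h`, `stderr`, `r2`, `n_points`.
#' @examples
#' d <- tibble::tibble(time_h = seq(0, 2, 0.5), od600 = 0.1 * 2^seq(0, 2, 0.5))
#' fit_growth_rate(d) # lambda = ln 2
#' @seealso [fit_growth_rates()] for many curves at once.
#' @export
fit_growth_rate <- function(data, od_window = c(0.1, 0.5)) {
  data <- as_tibble(data)
  miss <- setdiff(c("time_h", "od600"), names(data))
  if (length(miss) > 0) {
    ppa_abort(sprintf("`data` is missing column(s): %s.",
                      paste(miss, collapse = ", ")), "ppa_error_schema")
  }
  if (any(!is.finite(data$od600)) || any(data$od600 <= 0)) {
    ppa_abort("All od600 values must be positive.", "ppa_error_validation")
  }
  if (length(od_window) != 2 || od_window[1] >= od_window[2]) {
    ppa_abort("`od_window` must be c(low, high) with low < high.",
              "ppa_error_validation")
  }
  sub <- data[data$od600 >= od_window[1] & data$od600 <= od_window[2], ]
  if (nrow(sub) < 3) {
    ppa_abort(sprintf("Only %d point(s) fall in the OD window [%g, %g]; at least 3 are required.",
                      nrow(sub), od_window[1], od_window[2]),
              "ppa_error_insufficient_data")
  }
  fit <- lm(log(od600) ~ time_h, data = sub)
  lambda <- unname(coef(fit)[2])
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  # Constant OD: zero total variance makes r^2 undefined, not zero.
  if (sd(log(sub$od600)) == 0) {
    lambda <- 0
    r2 <- NA_real_
  }
  if (lambda < 0) {
    warn(sprintf("Fitted growth rate is negative (%.4g /h); reporting it unchanged.",
                 lambda), class = "ppa_warning_negative_rate")
  }
  tibble(
    lambda_per_h = lambda,
    stderr = unname(sm$coefficients["time_h", "Std. Error"]),
    r2 = r2,
    n_points = nrow(sub)
  )
}

#' Estimate growth rates for a table of many growth curves
#'
#' Applies [fit_growth_rate()] per culture, grouping by `sample_id` and
#' carrying `condition` / `inducer_uM` metadata through when present.
#' Each curve is fitted on its own; replicate averaging, if wanted, is an
#' explicit downstream step.
#'
#' @param data A growth-curve table as returned by
#'   `read_table(..., "growth_curves")`.
#' @inheritParams fit_growth_rate
#' @return A tibble with one row per `sample_id`: metadata plus
#'   `lambda_per_h`, `stderr`, `r2`, `n_points`.
#' @export
fit_growth_rates <- function(data, od_window = c(0.1, 0.5)) {
  data <- as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    ppa_abort("`data` must contain a `sample_id` column.", "ppa_error_schema")
  }
  meta_cols <- intersect(c("condition", "inducer_uM"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    dplyr::group_modify(~ fit_growth_rate(.x, od_window = od_window)) |>
    dplyr::ungroup()
}

#' Growth rates relative to the uninduced reference
#'
#' Normalises growth rates within a titration to the zero-inducer sample,
#' which maps to exactly 1. When a `condition` column is present the
#' normalisation is done per condition, mirroring how titration series are
#' compared across media.
#'
#' @param data A data frame with columns `inducer_uM` and `lambda_per_h`
#'   (optionally `condition`).
#' @param reference_uM Inducer concentration of the reference sample
#'   (default 0).
#' @return `data` with an added `rel_lambda` column; row order preserved.
#' @export
relative_growth_rates <- function(data, reference_uM = 0) {
  data <- as_tibble(data)
  miss <- setdiff(c("inducer_uM", "lambda_per_h"), names(data))
  if (length(miss) > 0) {
    ppa_abort(sprintf("`data` is missing column(s): %s.",
                      paste(miss, collapse = ", ")), "ppa_error_schema")
  }
  normalise <- function(d) {
    ref <- d$lambda_per_h[d$inducer_uM == reference_uM]
    if (length(ref) == 0) {
      ppa_abort(sprintf("No sample at the reference inducer level %g uM.",
                        reference_uM), "ppa_error_missing_reference")
    }
    lam_ref <- mean(ref)
    if (lam_ref == 0) {
      ppa_abort("Reference growth rate is zero; relative rates are undefined.",
                "ppa_error_division")
    }
    d$rel_lambda <- d$lambda_per_h / lam_ref
    d
  }
  if ("condition" %in% names(data)) {
    # split/modify/unsplit keeps the original row order within and across
    # conditions
    parts <- split(seq_len(nrow(data)), data$condition)
    out <- data
    out$rel_lambda <- NA_real_
    for (idx in parts) {
      out$rel_lambda[idx] <- normalise(data[idx, ])$rel_lambda
    }
    out
  } else {
    normalise(data)
  }
}
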