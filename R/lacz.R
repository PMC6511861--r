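#' Reduce beta-galactosidase colorimetric readings to Miller units
#'
#' Applies the classical ONPG-assay normalisation
#' `MU = 1000 * (OD420 - 1.75 * OD550) / (t_min * v_ml * OD600)`:
#' the 1.75 * OD550 term subtracts cell-debris scatter from the OD420
#' reading, and the denominator normalises by reaction time, assayed culture
#' volume and culture density. Blank-dominated readings can come out
#' negative; they are reported with a warning, not clamped, so that error
#' propagation through downstream averages is preserved.
#'
#' @param data A data frame with numeric columns `od420`, `od550`, `t_min`
#'   (reaction time, minutes), `v_ml` (culture volume, ml) and `od600`.
#' @return `data` with an added `miller` column.
#' @examples
#' miller_units(tibble::tibble(od420 = 0.9, od550 = 0.2,
#'                             t_min = 10, v_ml = 0.1, od600 = 0.4))
#' @export
miller_units <- function(data) {
  data <- as_tibble(data)
  miss <- setdiff(c("od420", "od550", "t_min", "v_ml", "od600"), names(data))
  if (length(miss) > 0) {
    ppa_abort(sprintf("`data` is missing column(s): %s.",
                      paste(miss, collapse = ", ")), "ppa_error_schema")
  }
  if (any(data$t_min <= 0) || any(data$v_ml <= 0) || any(data$od600 <= 0)) {
    ppa_abort("t_min, v_ml and od600 must all be positive.",
              "ppa_error_validation")
  }
  if (any(data$od420 < 0) || any(data$od550 < 0)) {
    ppa_abort("Absorbances must be non-negative.", "ppa_error_validation")
  }
  mu <- 1000 * (data$od420 - 1.75 * data$od550) /
    (data$t_min * data$v_ml * data$od600)
  if (any(mu < 0)) {
    warn(sprintf("%d reading(s) give negative Miller units (blank-dominated); reported unchanged.",
                 sum(mu < 0)), class = "ppa_warning_negative_miller")
  }
  dplyr::mutate(data, miller = mu)
}

#' Deduce the translational elongation rate from a LacZ induction curve
#'
#' Uses the square-root transform of the classical induction assay. After
#' inducer addition, no active LacZ exists until the first monomer is
#' completed at `t_first = lacz_len / ER`; from then on, accumulated activity
#' grows quadratically, so `sqrt(activity)` is linear in time with x-intercept
#' `t_first`. The procedure: (1) estimate the pre-induction baseline and its
#' spread from the initial flat segment; (2) mark the rise at the first point
#' exceeding baseline + `rise_sigma` * spread; (3) regress
#' `sqrt(activity - baseline)` on time over the post-rise points; (4) report
#' the x-intercept as `t_first_s` and `er_aa_s = lacz_len / t_first_s`.
#' The estimate is invariant to adding a constant baseline to the whole
#' series.
#'
#' @param data A data frame with numeric columns `time_s` (seconds since
#'   inducer addition, strictly increasing) and `activity` (arbitrary units,
#'   non-negative); at least 6 points.
#' @param constants A [ribosome_constants()] object (supplies `lacz_len`).
#' @param rise_sigma Rise-detection threshold in units of baseline spread
#'   (default 3).
#' @return A one-row tibble: `er_aa_s`, `t_first_s`, `fit_r_squared`,
#'   `n_fit` (points in the square-root regression).
#' @examples
#' tt <- seq(0, 300, 10)
#' d <- tibble::tibble(time_s = tt,
#'                     activity = ifelse(tt > 60, 2e-3 * (tt - 60)^2, 0))
#' estimate_elongation_rate(d) # t_first = 60 s, ER = 1023/60 aa/s
#' @export
estimate_elongation_rate <- function(data, constants = ribosome_constants(),
                                     rise_sigma = 3) {
  data <- as_tibble(data)
  miss <- setdiff(c("time_s", "activity"), names(data))
  if (length(miss) > 0) {
    ppa_abort(sprintf("`data` is missing column(s): %s.",
                      paste(miss, collapse = ", ")), "ppa_error_schema")
  }
  stopifnot(inherits(constants, "ribosome_constants"))
  n <- nrow(data)
  if (n < 6) {
    ppa_abort("An induction curve needs at least 6 points.",
              "ppa_error_insufficient_data")
  }
  if (any(diff(data$time_s) <= 0)) {
    ppa_abort("`time_s` must be strictly increasing.", "ppa_error_validation")
  }
  tt <- data$time_s
  aa <- data$activity

  # Grow the baseline prefix while the next point stays within
  # rise_sigma * spread of the running baseline; the first excursion marks
  # the rise. With a noiseless zero baseline (spread 0) any positive
  # activity triggers it.
  k <- min(3L, n)
  rise <- NA_integer_
  while (k < n) {
    base <- mean(aa[seq_len(k)])
    spread <- sd(aa[seq_len(k)])
    if (aa[k + 1L] > base + rise_sigma * spread) {
      rise <- k + 1L
      break
    }
    k <- k + 1L
  }
  if (is.na(rise)) {
    ppa_abort("Activity never rises above the baseline; no induction detected.",
              "ppa_error_no_induction")
  }
  baseline <- mean(aa[seq_len(rise - 1L)])

  post <- seq.int(rise, n)
  net <- aa[post] - baseline
  keep <- net > 0
  if (sum(keep) < 3) {
    ppa_abort("Fewer than 3 post-rise points with positive net activity.",
              "ppa_error_no_induction")
  }
  x <- tt[post][keep]
  y <- sqrt(net[keep])
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  if (b[2] <= 0) {
    ppa_abort("Square-root activity does not increase after the rise; no induction detected.",
              "ppa_error_no_induction")
  }
  t_first <- -b[1] / b[2]
  if (t_first <= 0) {
    ppa_abort("The fitted first-completion time is non-positive; the curve is inconsistent with a lag model.",
              "ppa_error_geometry")
  }
  tibble(
    er_aa_s = constants$lacz_len / t_first,
    t_first_s = t_first,
    fit_r_squared = suppressWarnings(summary(fit))$r.squared,
    n_fit = length(x)
  )
}

#' Active ribosome fraction from growth rate, R/P ratio and elongation rate
#'
#' Under flux balance, total protein synthesis must match growth:
#' each amino acid of protein requires `lambda / 3600` new amino acids per
#' second. The ribosome number per amino acid of total protein follows from
#' the RNA/protein ratio as `n = rp_ratio * f_rrna * m_aa / m_rrna`, and only
#' a fraction `f` of those ribosomes elongates at `er_aa_s`. Balancing the
#' two fluxes gives `f = (lambda / 3600) / (er_aa_s * n)`.
#'
#' @param lam Growth rate (1/h, >= 0; vectorised).
#' @param rp_ratio RNA/protein mass ratio (> 0; vectorised).
#' @param er_aa_s Translational elongation rate (amino acids/s, > 0).
#' @param constants A [ribosome_constants()] object.
#' @return Numeric vector of active fractions in `[0, 1]`. Values above
#'   1 + 1e-6 signal inputs that violate the assumed flux balance and raise
#'   an error; values within the tolerance band are clamped to 1.
#' @examples
#' active_ribosome_fraction(lam = 0.9, rp_ratio = 0.4, er_aa_s = 16.5)
#' @export
active_ribosome_fraction <- function(lam, rp_ratio, er_aa_s,
                                     constants = ribosome_constants()) {
  stopifnot(inherits(constants, "ribosome_constants"))
  if (any(lam < 0)) {
    ppa_abort("`lam` must be non-negative.", "ppa_error_validation")
  }
  if (any(rp_ratio <= 0) || any(er_aa_s <= 0)) {
    ppa_abort("`rp_ratio` and `er_aa_s` must be positive.",
              "ppa_error_validation")
  }
  n_rib <- rp_ratio * constants$f_rrna * constants$m_aa / constants$m_rrna
  f <- (lam / 3600) / (er_aa_s * n_rib)
  if (any(f > 1 + 1e-6)) {
    ppa_abort("Computed active fraction exceeds 1: the inputs violate the flux balance this deduction assumes.",
              "ppa_error_inconsistency")
  }
  pmin(f, 1)
}
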