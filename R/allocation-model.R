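#' Convert between RNA/protein ratio and ribosomal proteome fraction
#'
#' The RNA/protein mass ratio is a proxy for ribosome content; it converts to
#' the ribosome-affiliated proteome mass fraction as
#' `phi_R = rp_ratio * rho`. With the zero-growth intercept R/P = 0.56 of the
#' ppGpp-depletion growth law and rho = 0.76 this gives phi_R = 0.4256,
#' i.e. 43% of the proteome.
#'
#' @param rp_ratio RNA/protein mass ratio (non-negative, vectorised).
#' @param phi_R Ribosome-affiliated proteome fraction (vectorised).
#' @param rho Conversion factor, default 0.76.
#' @return Numeric vector: `phi_R` (resp. `rp_ratio`).
#' @examples
#' phi_R_from_rp(0.56, 0.76)        # 0.4256
#' percent_label(phi_R_from_rp(0.56))
#' @export
phi_R_from_rp <- function(rp_ratio, rho = 0.76) {
  ppa_stopifnot_scalar(rho, "rho", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(rp_ratio < 0, na.rm = TRUE)) {
    ppa_abort("`rp_ratio` must be non-negative.", "ppa_error_validation")
  }
  rp_ratio * rho
}

#' @rdname phi_R_from_rp
#' @export
rp_from_phi_R <- function(phi_R, rho = 0.76) {
  ppa_stopifnot_scalar(rho, "rho", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(phi_R < 0, na.rm = TRUE)) {
    ppa_abort("`phi_R` must be non-negative.", "ppa_error_validation")
  }
  phi_R / rho
}

#' Balanced-growth optimum of the allocation model
#'
#' Under balanced growth the translational flux `gamma * phi_R` and the
#' metabolic flux `nu * phi_M` are equal, and with the budget constraint
#' `phi_R + phi_M = phi_max` the steady state is unique:
#' `lambda* = gamma * nu * phi_max / (gamma + nu)`,
#' `phi_R* = nu * phi_max / (gamma + nu)`,
#' `phi_M* = gamma * phi_max / (gamma + nu)`.
#' This is also the allocation that maximises [perturbed_growth()].
#'
#' @param params An [allocation_params()] object.
#' @return A one-row tibble with columns `lambda`, `phi_R`, `phi_M`,
#'   `rp_ratio` (= `phi_R / rho`).
#' @examples
#' balanced_growth(allocation_params(gamma = 6, nu = 3, phi_max = 0.4))
#' @export
balanced_growth <- function(params) {
  stopifnot(inherits(params, "allocation_params"))
  denom <- params$gamma + params$nu
  phi_R <- params$nu * params$phi_max / denom
  phi_M <- params$gamma * params$phi_max / denom
  tibble(
    lambda = params$gamma * phi_R,
    phi_R = phi_R,
    phi_M = phi_M,
    rp_ratio = phi_R / params$rho
  )
}

#' Growth rate under a forced (ppGpp-set) ribosomal allocation
#'
#' When ppGpp pins the ribosomal fraction away from the optimum, steady-state
#' growth is set by whichever flux is limiting:
#' `lambda = min(gamma * phi_R, nu * (phi_max - phi_R))`.
#' High ppGpp (low `phi_R`) limits the protein-synthesis flux; low ppGpp
#' (high `phi_R`, compressed metabolic sector) limits the metabolic flux.
#' At `phi_R = phi_max` no metabolic proteins remain and growth stops.
#'
#' @param phi_R Forced ribosome-affiliated fraction, in `[0, phi_max]`
#'   (vectorised).
#' @param params An [allocation_params()] object.
#' @return Numeric vector of growth rates (1/h).
#' @examples
#' p <- allocation_params(gamma = 6, nu = 3, phi_max = 0.4)
#' perturbed_growth(c(0.05, 2 / 15, 0.3), p)
#' @export
perturbed_growth <- function(phi_R, params) {
  stopifnot(inherits(params, "allocation_params"))
  eps <- 1e-12
  if (any(phi_R < -eps | phi_R > params$phi_max + eps, na.rm = TRUE)) {
    ppa_abort("`phi_R` must lie in [0, phi_max].", "ppa_error_domain")
  }
  phi_R <- pmin(pmax(phi_R, 0), params$phi_max)
  pmin(params$gamma * phi_R, params$nu * (params$phi_max - phi_R))
}

#' Predicted activity of a constitutive or metabolic promoter
#'
#' Constitutive and metabolic promoters track the metabolic sector: their
#' activity is proportional to `phi_M`. Along the metabolic-limited branch
#' this makes activity increase linearly with growth rate; along the
#' translation-limited branch it decreases linearly, reproducing the mirror
#' patterns seen under ppGpp depletion and ppGpp overproduction.
#'
#' @param phi_M Metabolic proteome fraction (non-negative, vectorised).
#' @param scale Miller units per unit of proteome fraction (positive).
#' @return Numeric vector of predicted Miller units.
#' @examples
#' predict_promoter_activity(0.25, scale = 5000)
#' @export
predict_promoter_activity <- function(phi_M, scale) {
  ppa_stopifnot_scalar(scale, "scale", lower = 0, strict_lower = TRUE)
  if (any(phi_M < 0, na.rm = TRUE)) {
    ppa_abort("`phi_M` must be non-negative.", "ppa_error_validation")
  }
  scale * phi_M
}

#' Hill mapping from ppGpp level to ribosomal allocation
#'
#' The data establish that ribosomal allocation decreases monotonically with
#' the ppGpp level; a repressive Hill function is the simplest smooth
#' monotone parameterisation:
#' `phi_R(p) = phi_lo + (phi_hi - phi_lo) * K^n / (K^n + p^n)`.
#' At `p = 0` it returns `phi_hi`, at `p = K` the midpoint, and it decreases
#' strictly towards `phi_lo` as `p` grows.
#'
#' @param phi_lo,phi_hi Lower/upper plateau of `phi_R` (`phi_lo < phi_hi`).
#' @param K Half-repression ppGpp level (arbitrary units, > 0).
#' @param hill_n Hill coefficient (>= 1).
#' @return `hill_mapping()` returns an object of class `hill_mapping`;
#'   `ppgpp_to_phi_R()` returns a numeric vector of `phi_R` values.
#' @examples
#' m <- hill_mapping(phi_lo = 0.02, phi_hi = 0.13, K = 25, hill_n = 2)
#' ppgpp_to_phi_R(c(0, 25, 100), m)
#' @export
hill_mapping <- function(phi_lo, phi_hi, K, hill_n = 2) {
  ppa_stopifnot_scalar(phi_lo, "phi_lo", lower = 0)
  ppa_stopifnot_scalar(phi_hi, "phi_hi", lower = 0, upper = 1)
  ppa_stopifnot_scalar(K, "K", lower = 0, strict_lower = TRUE)
  ppa_stopifnot_scalar(hill_n, "hill_n", lower = 1)
  if (phi_lo >= phi_hi) {
    ppa_abort("`phi_lo` must be strictly below `phi_hi`.", "ppa_error_domain")
  }
  structure(list(phi_lo = phi_lo, phi_hi = phi_hi, K = K, hill_n = hill_n),
            class = "hill_mapping")
}

#' @rdname hill_mapping
#' @param ppgpp_au ppGpp level in arbitrary units (non-negative, vectorised).
#' @param mapping A `hill_mapping` object.
#' @export
ppgpp_to_phi_R <- function(ppgpp_au, mapping) {
  stopifnot(inherits(mapping, "hill_mapping"))
  if (any(ppgpp_au < 0, na.rm = TRUE)) {
    ppa_abort("`ppgpp_au` must be non-negative.", "ppa_error_domain")
  }
  kn <- mapping$K^mapping$hill_n
  mapping$phi_lo +
    (mapping$phi_hi - mapping$phi_lo) * kn / (kn + ppgpp_au^mapping$hill_n)
}

#' Fit a linear growth law
#'
#' Fits the empirical linear relation `y = intercept + slope * lambda` between
#' a proteome-sector proxy (RNA/protein ratio or promoter activity in Miller
#' units) and the exponential growth rate, by ordinary least squares. When the
#' response is the RNA/protein ratio the intercept is the classical `r_max`
#' (extrapolated R/P at zero growth) and `r_max * rho` estimates the
#' zero-growth ribosomal proteome fraction.
#'
#' @param data A data frame with a growth-rate column `lam` (1/h) and the
#'   response column named by `y`.
#' @param y Name of the response column (default `"rp_ratio"`).
#' @param rho Conversion used to report `r_max * rho` when `y` is
#'   `"rp_ratio"`; default 0.76.
#' @return An object of class `growth_law_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `n`, and (for an R/P response) `r_max` and
#'   `phi_R_zero_growth`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(lam = c(0.2, 0.5, 0.8), rp_ratio = 0.56 - 0.3 * c(0.2, 0.5, 0.8))
#' fit_growth_law(d)
#' @export
fit_growth_law <- function(data, y = "rp_ratio", rho = 0.76) {
  data <- as_tibble(data)
  if (!"lam" %in% names(data)) {
    ppa_abort("`data` must contain a `lam` column.", "ppa_error_schema")
  }
  if (!y %in% names(data)) {
    ppa_abort(sprintf("`data` has no response column `%s`.", y),
              "ppa_error_schema")
  }
  keep <- stats::complete.cases(data[c("lam", y)])
  data <- data[keep, ]
  if (nrow(data) < 3) {
    ppa_abort("A growth-law fit needs at least 3 complete points.",
              "ppa_error_insufficient_data")
  }
  lam <- data$lam
  if (diff(range(lam)) <= .Machine$double.eps * max(1, abs(max(lam)))) {
    ppa_abort("Growth rates are (numerically) all identical; the slope is unidentifiable.",
              "ppa_error_degenerate")
  }
  yv <- data[[y]]
  fit <- lm(yv ~ lam)
  sm <- suppressWarnings(summary(fit))
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    n = nrow(data),
    y_var = y,
    data = tibble(lam = lam, y = yv),
    model = fit
  )
  if (identical(y, "rp_ratio")) {
    out$r_max <- out$intercept
    out$phi_R_zero_growth <- out$intercept * rho
    out$rho <- rho
  }
  structure(out, class = "growth_law_fit")
}

#' @export
print.growth_law_fit <- function(x, ...) {
  cat(sprintf("<growth_law_fit> %s = %.5g %+.5g * lambda  (r^2 = %.4f, n = %d)\n",
              x$y_var, x$intercept, x$slope, x$r_squared, x$n))
  if (!is.null(x$r_max)) {
    cat(sprintf("  r_max = %.4g; zero-growth phi_R = %.4g (%s)\n",
                x$r_max, x$phi_R_zero_growth, percent_label(x$phi_R_zero_growth)))
  }
  invisible(x)
}

#' @rdname fit_growth_law
#' @param x A `growth_law_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_law_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, "Std. Error"])
  )
}

#' @rdname fit_growth_law
#' @export
glance.growth_law_fit <- function(x, ...) {
  out <- tibble(r_squared = x$r_squared, n = x$n, y_var = x$y_var)
  if (!is.null(x$r_max)) {
    out$r_max <- x$r_max
    out$phi_R_zero_growth <- x$phi_R_zero_growth
  }
  out
}

#' Recover allocation parameters from a two-direction titration
#'
#' Implements the growth-law reading of a paired ppGpp titration. Raising
#' ppGpp pushes samples onto the translation-limited branch
#' (`lambda = gamma * phi_R`); lowering it pushes them onto the
#' metabolic-limited branch (`lambda = nu * (phi_max - phi_R)`). The
#' procedure: (1) convert R/P to `phi_R` with `rho`; (2) fit each branch by
#' ordinary least squares; (3) read `gamma` as the slope of lambda versus
#' `phi_R` on the translation branch, `nu` as `-1/slope` and `phi_max` as the
#' zero-growth intercept of `phi_R` versus lambda on the metabolic branch;
#' (4) report the implied balanced-growth optimum and per-branch r-squared.
#'
#' @param data A data frame with columns `direction` (values `"ppgpp_up"`,
#'   `"ppgpp_down"`), `lam` (1/h) and `rp_ratio`; e.g. the output of
#'   [simulate_titration()] for both directions, row-bound.
#' @param rho R/P-to-`phi_R` conversion (default 0.76).
#' @param offset_up If `TRUE` (default) the translation-limited branch is
#'   fitted with a free intercept, which is reported so a nonzero R/P offset
#'   at zero growth stays visible; if `FALSE` the branch is forced through
#'   the origin, the strict reading of `lambda = gamma * phi_R`.
#' @return An object of class `allocation_fit`: recovered
#'   [allocation_params()] plus per-branch diagnostics. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' cfg <- sim_config(noise_cv = list(lam = 0, rp_ratio = 0, od600 = 0,
#'                                   miller = 0, induction = 0))
#' d <- dplyr::bind_rows(simulate_titration(cfg, "ppgpp_up"),
#'                       simulate_titration(cfg, "ppgpp_down"))
#' recover_parameters(d)
#' @export
recover_parameters <- function(data, rho = 0.76, offset_up = TRUE) {
  data <- as_tibble(data)
  need <- c("direction", "lam", "rp_ratio")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    ppa_abort(sprintf("`data` is missing column(s): %s.",
                      paste(miss, collapse = ", ")), "ppa_error_schema")
  }
  up <- dplyr::filter(data, .data$direction == "ppgpp_up")
  down <- dplyr::filter(data, .data$direction == "ppgpp_down")
  if (nrow(up) < 4 || nrow(down) < 4) {
    ppa_abort("Each titration direction needs at least 4 samples.",
              "ppa_error_insufficient_data")
  }

  up$phi_R <- phi_R_from_rp(up$rp_ratio, rho)
  down$phi_R <- phi_R_from_rp(down$rp_ratio, rho)

  # Branch sign check on the (lambda, R/P) slope before any parameter is read:
  # raising ppGpp must give a positive slope, lowering it a negative one.
  slope_sign <- function(d) sign(unname(coef(lm(d$rp_ratio ~ d$lam))[2]))
  if (slope_sign(up) <= 0) {
    ppa_abort("ppgpp_up samples do not show the positive (lambda, R/P) slope of a translation-limited branch.",
              "ppa_error_branch")
  }
  if (slope_sign(down) >= 0) {
    ppa_abort("ppgpp_down samples do not show the negative (lambda, R/P) slope of a metabolic-limited branch.",
              "ppa_error_branch")
  }

  fit_up <- if (offset_up) {
    lm(lam ~ phi_R, data = up)               # lambda = a + gamma * phi_R
  } else {
    lm(lam ~ phi_R - 1, data = up)           # strict lambda = gamma * phi_R
  }
  fit_down <- lm(phi_R ~ lam, data = down)   # phi_R = phi_max - lambda / nu
  gamma_hat <- unname(coef(fit_up)[["phi_R"]])
  nu_hat <- -1 / unname(coef(fit_down)[2])
  phi_max_hat <- unname(coef(fit_down)[1])

  params <- allocation_params(gamma = gamma_hat, nu = nu_hat,
                              phi_max = phi_max_hat, rho = rho)
  opt <- balanced_growth(params)
  structure(
    list(
      params = params,
      lambda_opt = opt$lambda,
      phi_R_opt = opt$phi_R,
      r_squared_up = suppressWarnings(summary(fit_up))$r.squared,
      r_squared_down = suppressWarnings(summary(fit_down))$r.squared,
      n_up = nrow(up),
      n_down = nrow(down),
      intercept_up = if (offset_up) unname(coef(fit_up)[1]) else 0,
      data = dplyr::bind_rows(up, down)
    ),
    class = "allocation_fit"
  )
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat("<allocation_fit> recovered three-sector parameters\n")
  cat(sprintf("  gamma = %.4g /h, nu = %.4g /h, phi_max = %.4g\n",
              x$params$gamma, x$params$nu, x$params$phi_max))
  cat(sprintf("  optimum: lambda* = %.4g /h at phi_R* = %.4g\n",
              x$lambda_opt, x$phi_R_opt))
  cat(sprintf("  branch fits: r^2(up) = %.4f (n = %d), r^2(down) = %.4f (n = %d)\n",
              x$r_squared_up, x$n_up, x$r_squared_down, x$n_down))
  invisible(x)
}

#' @rdname recover_parameters
#' @param x An `allocation_fit` object.
#' @param ... Unused.
#' @export
tidy.allocation_fit <- function(x, ...) {
  tibble(
    term = c("gamma", "nu", "phi_max", "lambda_opt", "phi_R_opt"),
    estimate = c(x$params$gamma, x$params$nu, x$params$phi_max,
                 x$lambda_opt, x$phi_R_opt)
  )
}

#' @rdname recover_parameters
#' @export
glance.allocation_fit <- function(x, ...) {
  tibble(
    r_squared_up = x$r_squared_up,
    r_squared_down = x$r_squared_down,
    n_up = x$n_up,
    n_down = x$n_down,
    lambda_opt = x$lambda_opt
  )
}
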