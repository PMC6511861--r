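#' Plot a fitted growth law
#'
#' Scatter of the response against growth rate with the fitted ordinary
#' least-squares line, annotated with the zero-growth intercept (`r_max`
#' when the response is the RNA/protein ratio).
#'
#' @param object A `growth_law_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$lam, y = .data$y)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = expression(paste("growth rate ", lambda, " (1/h)")),
      y = object$y_var,
      subtitle = sprintf("y = %.3g %+.3g lambda,  r² = %.3f",
                         object$intercept, object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-branch allocation fit
#'
#' Shows both titration branches in the (growth rate, phi_R) plane with the
#' recovered translation-limited and metabolic-limited growth laws and the
#' implied balanced-growth optimum.
#'
#' @param object An `allocation_fit` object from [recover_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allocation_fit <- function(object, ...) {
  p <- object$params
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$lam, y = .data$phi_R,
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = -object$intercept_up / p$gamma,
                         slope = 1 / p$gamma, linetype = 2) +
    ggplot2::geom_abline(intercept = p$phi_max, slope = -1 / p$nu,
                         linetype = 2) +
    ggplot2::annotate("point", x = object$lambda_opt, y = object$phi_R_opt,
                      shape = 8, size = 3) +
    ggplot2::labs(
      x = expression(paste("growth rate ", lambda, " (1/h)")),
      y = expression(phi[R]),
      colour = "titration",
      subtitle = sprintf("gamma = %.3g /h, nu = %.3g /h, phi_max = %.3g",
                         p$gamma, p$nu, p$phi_max)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the flux-limited growth curve over forced allocations
#'
#' Draws `lambda = min(gamma * phi_R, nu * (phi_max - phi_R))` over the full
#' allocation range, marking the balanced-growth optimum where the
#' translational and metabolic fluxes cross: allocations left of the peak are
#' translation-limited (the high-ppGpp regime), allocations right of it are
#' metabolism-limited (the low-ppGpp regime).
#'
#' @param params An [allocation_params()] object.
#' @param n Number of grid points (default 400).
#' @return A ggplot object.
#' @export
plot_perturbed_growth <- function(params, n = 400) {
  stopifnot(inherits(params, "allocation_params"))
  grid <- tibble(phi_R = seq(0, params$phi_max, length.out = n))
  grid$lambda <- perturbed_growth(grid$phi_R, params)
  opt <- balanced_growth(params)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi_R, y = .data$lambda)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = opt$phi_R, y = opt$lambda,
                      colour = "firebrick", size = 2.5) +
    ggplot2::labs(
      x = expression(paste("forced ribosomal fraction ", phi[R])),
      y = expression(paste(lambda, " (1/h)")),
      subtitle = sprintf("optimum: lambda* = %.3g /h at phi_R* = %.3g",
                         opt$lambda, opt$phi_R)
    ) +
    ggplot2::theme_minimal()
}
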