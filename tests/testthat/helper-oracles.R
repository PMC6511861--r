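# Independent least-squares oracle: closed-form normal-equation sums, no lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Grid-search oracle for the flux-limited growth maximum.
grid_opt_oracle <- function(gamma, nu, phi_max, step = 1e-5) {
  phi <- seq(0, phi_max, by = step)
  lam <- pmin(gamma * phi, nu * (phi_max - phi))
  i <- which.max(lam)
  c(lambda = lam[i], phi_R = phi[i])
}

# Exact square-law induction curve with optional multiplicative noise factors.
square_law_curve <- function(t_first = 60, t_grid = seq(0, 300, 10),
                             c_scale = 2e-3, factors = 1) {
  act <- ifelse(t_grid > t_first, c_scale * (t_grid - t_first)^2, 0)
  tibble::tibble(time_s = t_grid, activity = act * factors)
}

default_params <- function() allocation_params(gamma = 6, nu = 3, phi_max = 0.4)

zero_noise_config <- function(...) {
  sim_config(noise_cv = list(od600 = 0, rp_ratio = 0, lam = 0,
                             miller = 0, induction = 0), ...)
}
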