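test_that("R/P converts to phi_R by the rho factor", {
  expect_equal(phi_R_from_rp(0.56, 0.76), 0.4256, tolerance = 1e-12)
  expect_equal(percent_label(phi_R_from_rp(0.56, 0.76)), "43%")
  expect_identical(phi_R_from_rp(0, 0.76), 0)
  expect_equal(phi_R_from_rp(0.2, 0.76), 0.152, tolerance = 1e-12)
  expect_equal(rp_from_phi_R(phi_R_from_rp(0.37)), 0.37, tolerance = 1e-12)
  expect_error(phi_R_from_rp(-0.1), class = "ppa_error_validation")
})

test_that("balanced growth solves the flux balance in closed form", {
  sym <- balanced_growth(allocation_params(gamma = 4, nu = 4, phi_max = 0.4))
  expect_equal(sym$phi_R, 0.2)
  expect_equal(sym$phi_M, 0.2)
  expect_equal(sym$lambda, 4 * 0.2)

  opt <- balanced_growth(default_params())
  expect_equal(opt$lambda, 0.8, tolerance = 1e-12)
  expect_equal(opt$phi_R, 2 / 15, tolerance = 1e-12)
  expect_equal(6 * opt$phi_R, 3 * opt$phi_M, tolerance = 1e-12)

  # vanishing budget: growth rate goes to zero
  tiny <- balanced_growth(allocation_params(6, 3, phi_max = 1e-12))
  expect_lt(tiny$lambda, 1e-11)
})

test_that("balanced growth agrees with a grid-search oracle", {
  withr::with_seed(20190327, {
    for (i in 1:25) {
      g <- runif(1, 2, 8); n <- runif(1, 2, 8); pm <- runif(1, 0.3, 0.5)
      opt <- balanced_growth(allocation_params(g, n, pm))
      oracle <- grid_opt_oracle(g, n, pm, step = 1e-5)
      expect_equal(opt$lambda, unname(oracle["lambda"]), tolerance = 1e-4)
    }
  })
})

test_that("forced allocation growth is the limiting flux", {
  p <- default_params()
  # the two branches meet at the optimum
  opt <- balanced_growth(p)
  expect_equal(perturbed_growth(opt$phi_R, p), opt$lambda, tolerance = 1e-12)
  # hand evaluation of both branches
  expect_equal(perturbed_growth(0.3, p), 0.3)   # metabolic-limited (low ppGpp)
  expect_equal(perturbed_growth(0.05, p), 0.3)  # translation-limited (high ppGpp)
  # full R-sector leaves no metabolic proteins: growth stops
  expect_equal(perturbed_growth(p$phi_max, p), 0)
  expect_error(perturbed_growth(0.5, p), class = "ppa_error_domain")
  expect_error(perturbed_growth(-0.01, p), class = "ppa_error_domain")
})

test_that("forced growth never exceeds the optimum and is unimodal", {
  withr::with_seed(77, {
    for (i in 1:50) {
      p <- allocation_params(runif(1, 2, 8), runif(1, 2, 8), runif(1, 0.3, 0.5))
      opt <- balanced_growth(p)
      phi <- seq(0, p$phi_max, length.out = 501)
      lam <- perturbed_growth(phi, p)
      expect_true(all(lam <= opt$lambda + 1e-12))
      left <- phi < opt$phi_R - 1e-9
      right <- phi > opt$phi_R + 1e-9
      expect_true(all(diff(lam[left]) > 0))
      expect_true(all(diff(lam[right]) < 0))
      # conservation: phi_R + phi_M + phi_Q = 1 at the optimum
      expect_equal(opt$phi_R + opt$phi_M + p$phi_Q, 1, tolerance = 1e-9)
    }
  })
})

test_that("promoter activity tracks the metabolic sector linearly", {
  expect_equal(predict_promoter_activity(0, 5000), 0)
  p <- default_params()
  # metabolic branch: activity = (scale/nu) * lambda, positive linear
  lam <- c(0.2, 0.6)
  act_m <- predict_promoter_activity(lam / p$nu, 5000)
  expect_equal(act_m, 5000 / p$nu * lam, tolerance = 1e-12)
  # translation branch: activity = scale * (phi_max - lambda/gamma), negative linear
  act_t <- predict_promoter_activity(p$phi_max - lam / p$gamma, 5000)
  expect_equal(diff(act_t) / diff(lam), -5000 / p$gamma, tolerance = 1e-12)
})

test_that("the ppGpp-to-allocation Hill mapping is monotone with fixed limits", {
  m <- hill_mapping(phi_lo = 0.02, phi_hi = 0.13, K = 25, hill_n = 2)
  expect_equal(ppgpp_to_phi_R(0, m), 0.13)
  expect_equal(ppgpp_to_phi_R(25, m), (0.02 + 0.13) / 2, tolerance = 1e-12)
  withr::with_seed(4, p <- sort(runif(50, 0, 500)))
  phi <- ppgpp_to_phi_R(p, m)
  expect_true(all(diff(phi) < 0))
  expect_error(hill_mapping(0.2, 0.1, 10), class = "ppa_error_domain")
  expect_error(ppgpp_to_phi_R(-1, m), class = "ppa_error_domain")
})

test_that("growth-law fits recover exact lines and report r_max", {
  lam <- c(0.1, 0.3, 0.5, 0.9)
  d <- tibble::tibble(lam = lam, rp_ratio = 0.56 - 0.3 * lam)
  fit <- fit_growth_law(d)
  expect_equal(fit$slope, -0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.56, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$r_max, 0.56, tolerance = 1e-12)
  expect_equal(fit$phi_R_zero_growth, 0.4256, tolerance = 1e-12)

  # points generated by the metabolic-limited branch give intercept phi_max/rho
  p <- default_params()
  lam2 <- seq(0.1, 0.7, 0.2)
  d2 <- tibble::tibble(lam = lam2, rp_ratio = (p$phi_max - lam2 / p$nu) / p$rho)
  fit2 <- fit_growth_law(d2)
  expect_equal(fit2$intercept, p$phi_max / p$rho, tolerance = 1e-12)
  expect_equal(fit2$phi_R_zero_growth, p$phi_max, tolerance = 1e-12)
})

test_that("growth-law coefficients match an independent OLS oracle under noise", {
  withr::with_seed(20190327, {
    lam <- runif(12, 0.1, 1)
    y <- 0.56 - 0.3 * lam + rnorm(12, 0, 0.01)
  })
  fit <- fit_growth_law(tibble::tibble(lam = lam, rp_ratio = y))
  oracle <- ols_oracle(lam, y)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
})

test_that("degenerate growth-law inputs raise classed errors", {
  expect_error(fit_growth_law(tibble::tibble(lam = c(0.2, 0.3), rp_ratio = c(1, 2))),
               class = "ppa_error_insufficient_data")
  expect_error(fit_growth_law(tibble::tibble(lam = rep(0.4, 5), rp_ratio = runif(5))),
               class = "ppa_error_degenerate")
})

test_that("tidy and glance methods expose the fit as tibbles", {
  d <- tibble::tibble(lam = c(0.1, 0.4, 0.8), rp_ratio = 0.5 - 0.2 * c(0.1, 0.4, 0.8))
  fit <- fit_growth_law(d)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(0.5, -0.2), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$r_max, 0.5, tolerance = 1e-10)

  ex <- simulate_experiment(zero_noise_config())
  af <- recover_parameters(ex$physiology)
  expect_equal(tidy(af)$estimate[1:3], c(6, 3, 0.4), tolerance = 1e-9)
  expect_equal(glance(af)$lambda_opt, 0.8, tolerance = 1e-9)
})

test_that("parameter recovery is exact on noiseless titrations", {
  ex <- simulate_experiment(zero_noise_config())
  fit <- recover_parameters(ex$physiology)
  expect_equal(fit$params$gamma, 6, tolerance = 1e-9)
  expect_equal(fit$params$nu, 3, tolerance = 1e-9)
  expect_equal(fit$params$phi_max, 0.4, tolerance = 1e-9)
  expect_equal(fit$lambda_opt, 0.8, tolerance = 1e-9)
  expect_equal(fit$r_squared_up, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared_down, 1, tolerance = 1e-9)
})

test_that("the translation branch can be forced through the origin", {
  ex <- simulate_experiment(zero_noise_config())
  strict <- recover_parameters(ex$physiology, offset_up = FALSE)
  expect_equal(strict$params$gamma, 6, tolerance = 1e-9)
  expect_identical(strict$intercept_up, 0)
  free <- recover_parameters(ex$physiology, offset_up = TRUE)
  expect_equal(free$intercept_up, 0, tolerance = 1e-9)
})

test_that("branches sloping the same way are rejected, not silently reassigned", {
  ex <- simulate_experiment(zero_noise_config())
  up <- dplyr::filter(ex$physiology, direction == "ppgpp_up")
  relabelled <- dplyr::mutate(up, direction = "ppgpp_down")
  expect_error(recover_parameters(dplyr::bind_rows(up, relabelled)),
               class = "ppa_error_branch")
  expect_error(recover_parameters(up[1:3, ]),
               class = "ppa_error_insufficient_data")
})

test_that("autoplot methods return ggplot objects", {
  ex <- simulate_experiment(zero_noise_config())
  af <- recover_parameters(ex$physiology)
  expect_s3_class(autoplot(af), "ggplot")
  gl <- fit_growth_law(dplyr::filter(ex$physiology, direction == "ppgpp_down"))
  expect_s3_class(autoplot(gl), "ggplot")
  expect_s3_class(plot_perturbed_growth(default_params()), "ggplot")
})
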