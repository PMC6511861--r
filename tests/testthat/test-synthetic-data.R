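test_that("zero-noise titrations lie exactly on the model curves", {
  cfg <- zero_noise_config()
  up <- simulate_titration(cfg, "ppgpp_up")
  truth <- attr(up, "truth")
  expect_equal(up$lam, truth$lam_true, tolerance = 0)
  expect_equal(up$rp_ratio, truth$phi_R_true / cfg$params$rho, tolerance = 1e-12)
  expect_equal(up$miller,
               predict_promoter_activity(cfg$params$phi_max - truth$phi_R_true,
                                         cfg$promoter_scale),
               tolerance = 1e-12)
  # every phi_R respects the budget and the direction of the perturbation
  expect_true(all(truth$phi_R_true <= cfg$params$phi_max))
  down <- simulate_titration(cfg, "ppgpp_down")
  expect_true(all(attr(down, "truth")$phi_R_true >=
                    balanced_growth(cfg$params)$phi_R - 1e-9))
})

test_that("simulation is deterministic given (config, seed, direction)", {
  cfg <- sim_config()
  a <- simulate_titration(cfg, "ppgpp_up")
  b <- simulate_titration(cfg, "ppgpp_up")
  expect_identical(a, b)
  # different directions draw from different substreams
  d <- simulate_titration(cfg, "ppgpp_down")
  expect_false(identical(a$lam, d$lam))
  # adding a replicate leaves existing draws untouched
  cfg4 <- sim_config(n_replicates = 4)
  a4 <- simulate_titration(cfg4, "ppgpp_up")
  expect_equal(dplyr::filter(a4, replicate <= 3)$lam, a$lam, tolerance = 0)
})

test_that("ppGpp moves oppositely to inducer per direction and phi_R follows", {
  cfg <- sim_config()
  up <- dplyr::filter(simulate_titration(cfg, "ppgpp_up"), replicate == 1)
  expect_true(all(diff(up$ppgpp_au) > 0))
  down <- dplyr::filter(simulate_titration(cfg, "ppgpp_down"), replicate == 1)
  expect_true(all(diff(down$ppgpp_au) < 0))
  # higher ppGpp always means lower ribosomal allocation
  phi_up <- ppgpp_to_phi_R(up$ppgpp_au, cfg$mapping_up)
  expect_true(all(diff(phi_up) < 0))
})

test_that("generated tables satisfy the I/O schemas", {
  cfg <- sim_config()
  phys <- simulate_experiment(cfg)$physiology
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(phys, path)
  back <- read_table(path, "physiology")
  expect_equal(nrow(back), nrow(phys))

  curve <- simulate_growth_curve(0.9, times_h = window_times(0.9), seed = 3)
  write_table(curve, path)
  expect_equal(nrow(read_table(path, "growth_curves")), nrow(curve))

  ind <- simulate_induction_curve(16.5, seed = 3)
  write_table(ind, path)
  expect_equal(nrow(read_table(path, "induction")), nrow(ind))
})

test_that("growth curves round-trip through the rate estimator", {
  d <- simulate_growth_curve(log(2), od0 = 0.1, times_h = seq(0, 2, 0.25),
                             cv = 0, seed = 1)
  expect_equal(fit_growth_rate(d)$lambda_per_h, log(2), tolerance = 1e-12)

  # od0 = 0.015 at lambda = 0.9 crosses OD 0.1 near t = ln(0.1/0.015)/0.9 = 2.108 h
  d2 <- simulate_growth_curve(0.9, od0 = 0.015, times_h = seq(0, 4, 0.5),
                              cv = 0, seed = 1)
  inwin <- d2[d2$od600 >= 0.1 & d2$od600 <= 0.5, ]
  expect_true(all(inwin$time_h > 2.1))

  # Monte-Carlo: the mean recovered rate stays within 1% of truth
  lams <- vapply(1:100, function(i) {
    fit_growth_rate(simulate_growth_curve(
      0.9, od0 = 0.015, times_h = window_times(0.9), cv = 0.02,
      seed = 20190327 + i))$lambda_per_h
  }, numeric(1))
  expect_lt(abs(mean(lams) / 0.9 - 1), 0.01)
})

test_that("induction curves round-trip through the elongation estimator", {
  noiseless <- simulate_induction_curve(17.05, cv = 0, seed = 1)
  expect_equal(min(noiseless$time_s[noiseless$activity > 0]), 70) # lag 60 s, grid 10 s
  est <- estimate_elongation_rate(noiseless)
  expect_equal(est$er_aa_s, 17.05, tolerance = 1e-9)

  noisy <- estimate_elongation_rate(
    simulate_induction_curve(17.05, cv = 0.03, seed = 20190327))
  expect_equal(noisy$er_aa_s, 17.05, tolerance = 0.05)
})

test_that("the configured active fraction ties lambda, R/P and ER consistently", {
  cfg <- zero_noise_config(active_fraction_true = 0.85)
  up <- simulate_titration(cfg, "ppgpp_up")
  ok <- !is.na(up$er_aa_s)
  f <- active_ribosome_fraction(up$lam[ok], up$rp_ratio[ok], up$er_aa_s[ok],
                                cfg$constants)
  expect_equal(f, rep(0.85, sum(ok)), tolerance = 1e-9)
})

test_that("full pipeline closure: simulate, reduce, fit, recover", {
  # zero noise: every generating parameter comes back exactly
  ex0 <- simulate_experiment(zero_noise_config())
  fit0 <- recover_parameters(ex0$physiology)
  expect_equal(fit0$params$gamma, ex0$truth$gamma, tolerance = 1e-9)
  expect_equal(fit0$params$nu, ex0$truth$nu, tolerance = 1e-9)
  expect_equal(fit0$params$phi_max, ex0$truth$phi_max, tolerance = 1e-9)

  # default noise (CV 5% on lambda and R/P): within 5% relative
  ex <- simulate_experiment(sim_config())
  fit <- recover_parameters(ex$physiology)
  expect_lt(abs(fit$params$gamma / ex$truth$gamma - 1), 0.05)
  expect_lt(abs(fit$params$nu / ex$truth$nu - 1), 0.05)
  expect_lt(abs(fit$params$phi_max / ex$truth$phi_max - 1), 0.05)

  # and the fitted ppGpp-depletion growth law extrapolates to phi_max at zero noise
  down0 <- dplyr::filter(ex0$physiology, direction == "ppgpp_down")
  law <- fit_growth_law(down0)
  expect_equal(law$phi_R_zero_growth, ex0$truth$phi_max, tolerance = 1e-9)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(inducer_grid_uM = c(10, 5)),
               class = "ppa_error_validation")
  expect_error(sim_config(noise_cv = list(rp_ratio = -0.1)),
               class = "ppa_error_validation")
  expect_error(
    sim_config(mapping_down = hill_mapping(0.1, 0.45, K = 0.05)),
    class = "ppa_error_config")
})
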