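# Deterministic per-purpose substreams: each (purpose) string hashes to its
# own seed below 2^31, so adding replicates or measurement kinds never
# perturbs draws already taken by another purpose.
derive_seed <- function(seed, purpose) {
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) + h * 97) %% 2147483647)
}

# Multiplicative log-normal noise factors with unit mean and the requested
# coefficient of variation.
lognormal_factors <- function(n, cv, seed) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog)))
}

#' Configuration of a virtual ppGpp titration experiment
#'
#' Bundles everything needed to generate a complete synthetic titration:
#' the generating allocation parameters, the inducer-to-ppGpp dose maps and
#' ppGpp-to-allocation Hill mappings for both perturbation directions,
#' measurement noise levels, replication and seeding. The defaults emulate
#' an IPTG titration of a ppGpp synthetase (raising ppGpp, shrinking the
#' R-sector) and of a ppGpp hydrolase (lowering ppGpp, inflating the
#' R-sector), with the balanced optimum at `lambda* = 0.8` /h.
#'
#' @param params Generating [allocation_params()] (default gamma 6 /h,
#'   nu 3 /h, phi_max 0.4, rho 0.76).
#' @param mapping_up,mapping_down [hill_mapping()] objects taking the ppGpp
#'   level to `phi_R` for the synthetase (up) and hydrolase (down) titration.
#'   Defaults place the uninduced sample at the balanced optimum and drive
#'   `phi_R` towards 0.02 (up) or 0.39 (down) at full induction.
#' @param inducer_grid_uM Increasing inducer concentrations, uM.
#' @param inducer_to_ppgpp Per-direction log-linear dose maps,
#'   `list(up = list(base_au, fold_per_decade), down = ...)`:
#'   `ppgpp = base_au * fold_per_decade ^ log10(1 + inducer)`.
#' @param noise_cv Named list of coefficients of variation for `od600`,
#'   `rp_ratio`, `lam`, `miller` and `induction` measurements.
#' @param n_replicates Replicate cultures per inducer level (default 3, as
#'   in triplicate assays).
#' @param seed Base seed for all substreams (default 20190327).
#' @param er_true_aa_s Elongation rate used when synthesising induction
#'   curves (default 16.5 aa/s).
#' @param active_fraction_true Active ribosome fraction used to tie growth
#'   rate, R/P and per-sample elongation rate consistently (default 0.85).
#' @param promoter_scale Miller units per unit of metabolic proteome
#'   fraction for the constitutive reporter (default 5000).
#' @param promoter_name Reporter promoter label (default `"PtetO"`).
#' @param constants A [ribosome_constants()] object used when tying
#'   elongation rates to growth rate and R/P.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params = allocation_params(gamma = 6, nu = 3,
                                                  phi_max = 0.4, rho = 0.76),
                       mapping_up = NULL,
                       mapping_down = NULL,
                       inducer_grid_uM = c(0, 5, 10, 20, 30, 40, 60, 100),
                       inducer_to_ppgpp = list(
                         up = list(base_au = 1, fold_per_decade = 10),
                         down = list(base_au = 1, fold_per_decade = 0.1)
                       ),
                       noise_cv = list(),
                       n_replicates = 3,
                       seed = 20190327,
                       er_true_aa_s = 16.5,
                       active_fraction_true = 0.85,
                       promoter_scale = 5000,
                       promoter_name = "PtetO",
                       constants = ribosome_constants()) {
  stopifnot(inherits(params, "allocation_params"))
  opt <- balanced_growth(params)
  if (is.null(mapping_up)) {
    # Uninduced ppGpp (base_au) sits far below K: phi_R starts at the
    # optimum and collapses towards 0.02 over the inducer range.
    mapping_up <- hill_mapping(phi_lo = 0.02, phi_hi = opt$phi_R,
                               K = 28, hill_n = 4)
  }
  if (is.null(mapping_down)) {
    # Mirrored: uninduced ppGpp sits far above K; depleting ppGpp inflates
    # phi_R from the optimum towards 0.39.
    mapping_down <- hill_mapping(phi_lo = opt$phi_R, phi_hi = 0.39,
                                 K = 0.05, hill_n = 2)
  }
  stopifnot(inherits(mapping_up, "hill_mapping"),
            inherits(mapping_down, "hill_mapping"))
  if (any(diff(inducer_grid_uM) <= 0) || any(inducer_grid_uM < 0)) {
    ppa_abort("`inducer_grid_uM` must be non-negative and increasing.",
              "ppa_error_validation")
  }
  cv <- utils::modifyList(config_defaults()$noise_cv, noise_cv)
  if (any(unlist(cv) < 0)) {
    ppa_abort("Noise CVs must be non-negative.", "ppa_error_validation")
  }
  ppa_stopifnot_scalar(n_replicates, "n_replicates", lower = 1)
  ppa_stopifnot_scalar(seed, "seed", lower = 0, upper = 2^31 - 1)
  ppa_stopifnot_scalar(er_true_aa_s, "er_true_aa_s", lower = 0,
                       strict_lower = TRUE)
  ppa_stopifnot_scalar(active_fraction_true, "active_fraction_true",
                       lower = 0, upper = 1, strict_lower = TRUE)
  ppa_stopifnot_scalar(promoter_scale, "promoter_scale", lower = 0,
                       strict_lower = TRUE)
  if (max(mapping_up$phi_hi, mapping_down$phi_hi) > params$phi_max) {
    ppa_abort("A ppGpp-to-phi_R mapping exceeds phi_max.", "ppa_error_config")
  }
  structure(
    list(params = params, mapping_up = mapping_up,
         mapping_down = mapping_down,
         inducer_grid_uM = inducer_grid_uM,
         inducer_to_ppgpp = inducer_to_ppgpp,
         noise_cv = cv, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         er_true_aa_s = er_true_aa_s,
         active_fraction_true = active_fraction_true,
         promoter_scale = promoter_scale,
         promoter_name = promoter_name,
         constants = constants),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d inducer levels x %d replicates, seed %d\n",
              length(x$inducer_grid_uM), x$n_replicates, x$seed))
  cat(sprintf("  generating gamma = %g, nu = %g, phi_max = %g, rho = %g\n",
              x$params$gamma, x$params$nu, x$params$phi_max, x$params$rho))
  invisible(x)
}

#' Simulate one direction of a ppGpp titration
#'
#' Generates the physiology table of a virtual titration: for each inducer
#' level and replicate, the ppGpp level follows the direction's log-linear
#' dose map, the ribosomal allocation follows its Hill mapping, the growth
#' rate follows the flux-limited predictor [perturbed_growth()], the R/P
#' ratio is `phi_R / rho`, and the constitutive reporter activity is
#' proportional to the metabolic fraction. Measured quantities carry
#' multiplicative log-normal noise at the configured CVs; per-sample
#' elongation rates are tied to growth rate and R/P through the configured
#' active ribosome fraction. Output is deterministic given (config, seed,
#' direction).
#'
#' @param config A [sim_config()] object.
#' @param direction `"ppgpp_up"` (synthetase induction) or `"ppgpp_down"`
#'   (hydrolase induction).
#' @return A tibble with one row per sample: `sample_id`, `direction`,
#'   `inducer_uM`, `replicate`, `ppgpp_au`, `lam`, `rp_ratio`, `promoter`,
#'   `miller`, `er_aa_s`. The noiseless generating values are attached as
#'   the `"truth"` attribute (a tibble with `phi_R_true`, `lam_true`,
#'   `rp_true`, `miller_true`).
#' @examples
#' simulate_titration(sim_config(), "ppgpp_up")
#' @export
simulate_titration <- function(config, direction = c("ppgpp_up", "ppgpp_down")) {
  stopifnot(inherits(config, "sim_config"))
  direction <- match.arg(direction)
  p <- config$params
  mapping <- if (direction == "ppgpp_up") config$mapping_up else config$mapping_down
  dose <- if (direction == "ppgpp_up") config$inducer_to_ppgpp$up else config$inducer_to_ppgpp$down

  grid <- tidyr::expand_grid(
    replicate = seq_len(config$n_replicates),
    inducer_uM = config$inducer_grid_uM
  )
  ppgpp <- dose$base_au * dose$fold_per_decade^(log10(1 + grid$inducer_uM))
  phi_R <- ppgpp_to_phi_R(ppgpp, mapping)
  if (any(phi_R > p$phi_max)) {
    ppa_abort("The ppGpp mapping produces phi_R above phi_max.",
              "ppa_error_config")
  }
  lam_true <- perturbed_growth(phi_R, p)
  rp_true <- phi_R / p$rho
  miller_true <- predict_promoter_activity(p$phi_max - phi_R,
                                           config$promoter_scale)
  # Per-sample elongation rate implied by the flux balance at the configured
  # active fraction, so active_ribosome_fraction() round-trips exactly.
  kc <- config$constants
  n_rib <- rp_true * kc$f_rrna * kc$m_aa / kc$m_rrna
  er_true <- ifelse(lam_true > 0 & rp_true > 0,
                    (lam_true / 3600) / (config$active_fraction_true * n_rib),
                    NA_real_)

  nl <- length(config$inducer_grid_uM)
  noise_for <- function(purpose, cv) {
    unlist(lapply(seq_len(config$n_replicates), function(r) {
      lognormal_factors(nl, cv, derive_seed(config$seed,
                                            paste(direction, purpose, r)))
    }))
  }
  out <- tibble(
    sample_id = sprintf("%s_i%03d_r%d",
                        sub("ppgpp_", "", direction),
                        match(grid$inducer_uM, config$inducer_grid_uM),
                        grid$replicate),
    direction = direction,
    inducer_uM = grid$inducer_uM,
    replicate = grid$replicate,
    ppgpp_au = ppgpp,
    lam = lam_true * noise_for("lam", config$noise_cv$lam),
    rp_ratio = rp_true * noise_for("rp_ratio", config$noise_cv$rp_ratio),
    promoter = config$promoter_name,
    miller = miller_true * noise_for("miller", config$noise_cv$miller),
    er_aa_s = er_true
  )
  attr(out, "truth") <- tibble(
    phi_R_true = phi_R, lam_true = lam_true,
    rp_true = rp_true, miller_true = miller_true
  )
  out
}

#' Simulate an exponential OD600 growth curve
#'
#' `OD(t) = od0 * exp(lam * t)` with multiplicative log-normal measurement
#' noise; deterministic given `seed`.
#'
#' @param lam Growth rate (1/h, >= 0).
#' @param od0 Initial OD600 (default 0.015, a typical inoculation density).
#' @param times_h Sampling times in hours.
#' @param cv Coefficient of variation of the OD noise (default 0.02).
#' @param seed Integer seed.
#' @param sample_id,condition,inducer_uM Metadata carried into the output.
#' @return A growth-curve tibble (`sample_id`, `condition`, `inducer_uM`,
#'   `time_h`, `od600`).
#' @examples
#' simulate_growth_curve(0.9, times_h = seq(0, 4, 0.5), cv = 0, seed = 1)
#' @export
simulate_growth_curve <- function(lam, od0 = 0.015,
                                  times_h = seq(0, 4, by = 0.5),
                                  cv = 0.02, seed = 20190327,
                                  sample_id = "sim", condition = "simulated",
                                  inducer_uM = 0) {
  ppa_stopifnot_scalar(lam, "lam", lower = 0)
  ppa_stopifnot_scalar(od0, "od0", lower = 0, strict_lower = TRUE)
  if (any(diff(times_h) <= 0)) {
    ppa_abort("`times_h` must be strictly increasing.", "ppa_error_validation")
  }
  od <- od0 * exp(lam * times_h) *
    lognormal_factors(length(times_h), cv, derive_seed(seed, "od600"))
  tibble(sample_id = sample_id, condition = condition,
         inducer_uM = inducer_uM, time_h = times_h, od600 = od)
}

#' Time grid whose noiseless OD600 values span the fitting window
#'
#' Convenience for generating curves with a prescribed number of points
#' inside the exponential-fit OD window: returns `n` times equally spaced
#' between the crossings of `od_window[1]` and `od_window[2]`.
#'
#' @param lam Growth rate (1/h, > 0).
#' @param od0 Initial OD600.
#' @param od_window OD600 window, default `c(0.1, 0.5)`.
#' @param n Number of points (default 8, the upper end of typical practice).
#' @return Numeric vector of times (h).
#' @export
window_times <- function(lam, od0 = 0.015, od_window = c(0.1, 0.5), n = 8) {
  ppa_stopifnot_scalar(lam, "lam", lower = 0, strict_lower = TRUE)
  seq(log(od_window[1] / od0), log(od_window[2] / od0), length.out = n) / lam
}

#' Simulate a LacZ induction curve
#'
#' Activity is zero until the first LacZ monomer is completed at
#' `t_first = lacz_len / er_aa_s`, then grows as
#' `c_scale * (t - t_first)^2`, with multiplicative log-normal noise on the
#' positive part; deterministic given `seed`.
#'
#' @param er_aa_s True elongation rate (aa/s, > 0).
#' @param t_grid_s Sampling times (s since induction).
#' @param c_scale Quadratic-growth scale (activity units / s^2).
#' @param cv Noise coefficient of variation (default 0.03).
#' @param seed Integer seed.
#' @param constants A [ribosome_constants()] object (supplies `lacz_len`).
#' @return An induction-curve tibble (`time_s`, `activity`).
#' @examples
#' simulate_induction_curve(17.05, cv = 0, seed = 1) # lag = 60 s
#' @export
simulate_induction_curve <- function(er_aa_s, t_grid_s = seq(0, 300, by = 10),
                                     c_scale = 2e-3, cv = 0.03,
                                     seed = 20190327,
                                     constants = ribosome_constants()) {
  ppa_stopifnot_scalar(er_aa_s, "er_aa_s", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(constants, "ribosome_constants"))
  if (any(diff(t_grid_s) <= 0)) {
    ppa_abort("`t_grid_s` must be strictly increasing.", "ppa_error_validation")
  }
  t_first <- constants$lacz_len / er_aa_s
  act <- ifelse(t_grid_s > t_first, c_scale * (t_grid_s - t_first)^2, 0)
  act <- act * lognormal_factors(length(act), cv, derive_seed(seed, "induction"))
  tibble(time_s = t_grid_s, activity = act)
}

#' Simulate a complete two-direction titration experiment
#'
#' Runs [simulate_titration()] for both perturbation directions and returns
#' the row-bound physiology table together with the generating truth, ready
#' for [recover_parameters()] and the growth-law fits.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `physiology` (tibble over both directions)
#'   and `truth` (the generating parameters as a named list).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  phys <- dplyr::bind_rows(
    simulate_titration(config, "ppgpp_up"),
    simulate_titration(config, "ppgpp_down")
  )
  list(
    physiology = phys,
    truth = list(
      gamma = config$params$gamma,
      nu = config$params$nu,
      phi_max = config$params$phi_max,
      rho = config$params$rho,
      er_true_aa_s = config$er_true_aa_s,
      active_fraction_true = config$active_fraction_true,
      seed = config$seed
    )
  )
}
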