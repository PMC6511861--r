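# Tabular schemas. Units are fixed by column name: time_h hours, time_s
# seconds, inducer_uM micromolar, t_min minutes, v_ml millilitres.
ppa_schemas <- list(
  growth_curves = list(
    required = c("sample_id", "condition", "inducer_uM", "time_h", "od600"),
    character = c("sample_id", "condition")
  ),
  physiology = list(
    required = c("sample_id", "lam", "rp_ratio", "ppgpp_au"),
    optional = c("direction", "inducer_uM", "replicate", "promoter", "miller",
                 "er_aa_s"),
    character = c("sample_id", "direction", "promoter")
  ),
  induction = list(
    required = c("time_s", "activity"),
    character = character(0)
  ),
  assay = list(
    required = c("od420", "od550", "t_min", "v_ml", "od600"),
    optional = c("sample_id"),
    character = c("sample_id")
  )
)

#' Read a validated analysis table
#'
#' Reads one of the four tabular input kinds (comma-separated, header
#' required, UTF-8, "." decimal separator) and validates every row against
#' the type invariants of its schema. Extra columns are ignored; a missing
#' required column, a non-numeric cell or an invariant violation raises a
#' classed error that names the offending column or row.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"growth_curves"` (columns `sample_id`, `condition`,
#'   `inducer_uM`, `time_h`, `od600`), `"physiology"` (`sample_id`, `lam`,
#'   `rp_ratio`, `ppgpp_au`, optionally `direction`, `promoter`, `miller`,
#'   ...), `"induction"` (`time_s`, `activity`) or `"assay"` (`od420`,
#'   `od550`, `t_min`, `v_ml`, `od600`).
#' @return A tibble of validated records, in file order.
#' @seealso [write_table()]
#' @export
read_table <- function(path,
                       schema = c("growth_curves", "physiology",
                                  "induction", "assay")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    ppa_abort(sprintf("File not found: %s", path), "ppa_error_io")
  }
  sc <- ppa_schemas[[schema]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(sc$required, header)
  if (length(miss) > 0) {
    ppa_abort(sprintf("Schema '%s': missing required column(s): %s.",
                      schema, paste(miss, collapse = ", ")),
              "ppa_error_schema")
  }
  keep <- intersect(c(sc$required, sc$optional), header)
  types <- setNames(
    lapply(keep, function(cl) {
      if (cl %in% sc$character) readr::col_character() else readr::col_double()
    }),
    keep
  )
  # malformed cells are re-raised as classed parse errors below, so readr's
  # own parsing-issues warning is redundant
  df <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols_only, types),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    ppa_abort(sprintf("Schema '%s': non-numeric or malformed cell at row %d.",
                      schema, probs$row[1]),
              "ppa_error_parse")
  }
  df <- df[keep]
  validate_table(df, schema)
  df
}

# Row-level invariant checks; row numbers refer to data rows (header excluded).
validate_table <- function(df, schema) {
  bad_row <- function(ok, what) {
    if (any(!ok, na.rm = FALSE)) {
      i <- which(!ok | is.na(ok))[1]
      ppa_abort(sprintf("Schema '%s': %s (row %d).", schema, what, i),
                "ppa_error_validation")
    }
  }
  if (schema == "growth_curves") {
    bad_row(!is.na(df$od600) & df$od600 > 0, "od600 must be positive")
    bad_row(!is.na(df$time_h), "time_h must be numeric")
    incr <- df |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop")
    if (any(!incr$ok)) {
      ppa_abort(sprintf("Schema 'growth_curves': time points must be strictly increasing within sample '%s'.",
                        incr$sample_id[!incr$ok][1]),
                "ppa_error_validation")
    }
  } else if (schema == "physiology") {
    bad_row(!is.na(df$lam) & df$lam >= 0, "lam must be >= 0")
    bad_row(!is.na(df$rp_ratio) & df$rp_ratio >= 0, "rp_ratio must be >= 0")
    bad_row(!is.na(df$ppgpp_au) & df$ppgpp_au >= 0, "ppgpp_au must be >= 0")
  } else if (schema == "induction") {
    bad_row(!is.na(df$activity) & df$activity >= 0, "activity must be >= 0")
    if (any(diff(df$time_s) <= 0)) {
      ppa_abort("Schema 'induction': time_s must be strictly increasing.",
                "ppa_error_validation")
    }
  } else if (schema == "assay") {
    bad_row(!is.na(df$od420) & df$od420 >= 0, "od420 must be >= 0")
    bad_row(!is.na(df$od550) & df$od550 >= 0, "od550 must be >= 0")
    bad_row(!is.na(df$t_min) & df$t_min > 0, "t_min must be positive")
    bad_row(!is.na(df$v_ml) & df$v_ml > 0, "v_ml must be positive")
    bad_row(!is.na(df$od600) & df$od600 > 0, "od600 must be positive")
  }
  invisible(df)
}

#' Write an analysis table
#'
#' Writes a tibble as CSV with full floating-point precision, so that
#' `read_table(write_table(x))` reproduces `x` (doubles round-trip exactly;
#' readr writes the shortest representation that parses back to the same
#' value).
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    params = list(gamma = 6, nu = 3, phi_max = 0.40, rho = 0.76),
    constants = list(f_rrna = 0.86, m_aa = 109, m_rrna = 1.507e6,
                     lacz_len = 1023),
    noise_cv = list(od600 = 0.02, rp_ratio = 0.05, lam = 0.05,
                    miller = 0.05, induction = 0.03),
    od_window = c(0.1, 0.5),
    seed = 20190327
  )
}

#' Load a run configuration
#'
#' Reads a YAML run configuration with sections `params` (allocation model),
#' `constants` (ribosome/reporter constants), `noise_cv` (per-measurement
#' coefficients of variation), `od_window` and `seed`. Absent keys take the
#' documented defaults (`rho` 0.76, `phi_max` 0.40, OD window `[0.1, 0.5]`,
#' seed 20190327); unknown keys are rejected rather than silently ignored,
#' and out-of-range values raise validation errors.
#'
#' @param path Path to a YAML file, or `NULL` for the pure defaults.
#' @return An object of class `run_config`: a named list with elements
#'   `params` ([allocation_params()]), `constants` ([ribosome_constants()]),
#'   `noise_cv`, `od_window`, `seed`.
#' @seealso [write_config()]
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      ppa_abort(sprintf("Config file not found: %s", path), "ppa_error_io")
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      ppa_abort(sprintf("Unknown config key(s): %s.",
                        paste(unknown, collapse = ", ")), "ppa_error_config")
    }
    for (sec in names(user)) {
      if (is.list(cfg[[sec]])) {
        bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(bad) > 0) {
          ppa_abort(sprintf("Unknown key(s) in config section '%s': %s.",
                            sec, paste(bad, collapse = ", ")),
                    "ppa_error_config")
        }
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  params <- allocation_params(gamma = cfg$params$gamma, nu = cfg$params$nu,
                              phi_max = cfg$params$phi_max,
                              rho = cfg$params$rho)
  constants <- ribosome_constants(f_rrna = cfg$constants$f_rrna,
                                  m_aa = cfg$constants$m_aa,
                                  m_rrna = cfg$constants$m_rrna,
                                  lacz_len = cfg$constants$lacz_len)
  if (any(unlist(cfg$noise_cv) < 0)) {
    ppa_abort("Noise CVs must be non-negative.", "ppa_error_validation")
  }
  win <- as.numeric(unlist(cfg$od_window))
  if (length(win) != 2 || any(win <= 0) || win[1] >= win[2]) {
    ppa_abort("`od_window` must be two increasing positive numbers.",
              "ppa_error_validation")
  }
  seed <- cfg$seed
  ppa_stopifnot_scalar(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(
    list(params = params, constants = constants, noise_cv = cfg$noise_cv,
         od_window = win, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Write a run configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))` yields
#' identical parameters (idempotence of config round-trips).
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    params = config$params[c("gamma", "nu", "phi_max", "rho")],
    constants = unclass(config$constants),
    noise_cv = config$noise_cv,
    od_window = as.numeric(config$od_window),
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records the parameters, seed and package version of an analysis run next
#' to its CSV outputs, so a result can always be tied to the configuration
#' that produced it.
#'
#' @param config A `run_config` object.
#' @param path Output path (`.json`).
#' @param extra Optional named list of additional fields to record.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "run_config"))
  out <- c(list(
    params = config$params[c("gamma", "nu", "phi_max", "phi_Q", "rho")],
    constants = unclass(config$constants),
    noise_cv = config$noise_cv,
    od_window = config$od_window,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ppgppalloc"))
  ), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
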