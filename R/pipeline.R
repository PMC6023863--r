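# Run-configuration surface: every pm_* command takes a config (a named list
# or a path to a JSON file), writes machine-readable outputs into
# config$output_dir, logs every parameter used, and returns the output paths
# invisibly. All commands are deterministic for a fixed config and seed.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_io(sprintf("no such config file: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort_validation("config must be a list or a JSON path")
  config
}

config_defaults <- function(config, defaults) {
  utils::modifyList(defaults, config)
}

ensure_output_dir <- function(config) {
  if (is.null(config$output_dir)) abort_validation("config needs an `output_dir`")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  config$output_dir
}

log_run <- function(out_dir, command, config) {
  entry <- list(
    package = "photomotion",
    version = as.character(utils::packageVersion("photomotion")),
    command = command,
    seed = config$seed,
    config = config
  )
  path <- file.path(out_dir, paste0(command, "_log.json"))
  jsonlite::write_json(entry, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  message(sprintf("[photomotion] %s: logged parameters to %s", command, path))
  invisible(path)
}

resolve_conditions <- function(config) {
  if (!is.null(config$conditions_path)) {
    read_photo_conditions(config$conditions_path)
  } else if (!is.null(config$conditions)) {
    do.call(photo_conditions, config$conditions)
  } else {
    preset_photo_conditions()
  }
}

#' Run-configuration commands
#'
#' File-based entry points tying the modules into a workflow. Each command
#' reads a config (named list or JSON path), validates it, computes with the
#' package functions, writes CSV/JSON outputs plus a parameter log into
#' `output_dir`, and returns the output paths invisibly. A thin command-line
#' wrapper over these functions ships in `inst/cli/photomotion.R`.
#'
#' * `pm_fixtures()`: materializes the preset library (benzene photokinetic
#'   series + manifest + conditions, share datasets for every condition
#'   preset, a thermal decay, a two-component spectra series).
#' * `pm_simulate()`: forward photokinetic simulation from a config.
#' * `pm_fit_markov()`: global transition-matrix fit from a manifest.
#' * `pm_fit_qy()`: quantum-yield estimation from a manifest + conditions.
#' * `pm_thermal()`: reversible-kinetics fit plus Eyring barrier/half-life.
#' * `pm_spectra()`: isosbestic detection and the two-state rank test.
#' * `pm_report()`: fits everything and bundles a quantum-yield table,
#'   transition matrix and propensity table into one report.
#'
#' @param config Named list or path to a JSON config. Common fields:
#'   `output_dir` (required), `seed` (default 20180628). See the worked
#'   examples in the package vignette for per-command fields.
#' @return Invisibly, a named list of output file paths.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pm_fixtures <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, sigma = 0.01,
                                 times_min = 0:30))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "fixtures", config)

  cond <- preset_photo_conditions()
  write_photo_conditions(cond, file.path(out_dir, "conditions_benzene.json"))
  phot <- generate_photokinetic_dataset(
    starts = isomer_levels(), times_min = config$times_min,
    sigma = config$sigma, seed = config$seed
  )
  series_paths <- purrr::map_chr(isomer_levels(), function(s) {
    p <- file.path(out_dir, sprintf("benzene_start_%s.csv", s))
    write_composition_series(dplyr::filter(phot, .data$start == s), p)
    basename(p)
  })
  manifest <- list(
    dt = 1,
    series = purrr::map2(series_paths, isomer_levels(), function(p, s) {
      list(path = p, start = s, label = paste0("start_", s))
    })
  )
  manifest_path <- file.path(out_dir, "benzene_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  share_paths <- purrr::map_chr(motion_share_presets()$label, function(lab) {
    ds <- generate_share_dataset(lab, sigma = config$sigma, seed = config$seed)
    p <- file.path(out_dir, sprintf("share_%s.csv", lab))
    write_composition_series(ds, p)
    p
  })

  thermal <- generate_thermal_dataset(
    k_fwd = 1e-5, k_rev = 1e-5, temperature = 355.15,
    times_s = seq(0, 2e5, length.out = 40), sigma = config$sigma,
    seed = config$seed
  )
  thermal_path <- file.path(out_dir, "thermal_AB_82C.csv")
  readr::write_csv(thermal, thermal_path)

  spectra <- generate_spectra_dataset(sigma = 0, seed = config$seed)
  spectra_path <- file.path(out_dir, "spectra_two_state.csv")
  write_spectra_series(spectra, spectra_path)

  invisible(list(
    conditions = file.path(out_dir, "conditions_benzene.json"),
    manifest = manifest_path,
    series = file.path(out_dir, series_paths),
    shares = share_paths, thermal = thermal_path, spectra = spectra_path
  ))
}

#' @rdname pipeline
#' @export
pm_simulate <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, sigma = 0,
                                 start = "A", times_min = 0:30))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "simulate", config)
  cond <- resolve_conditions(config)
  phi <- if (!is.null(config$phi)) {
    quantum_yield_matrix(matrix(unlist(config$phi), 4L, 4L, byrow = TRUE))
  } else {
    preset_quantum_yields()
  }
  ds <- generate_photokinetic_dataset(
    phi = phi, cond = cond, starts = config$start,
    times_min = config$times_min, sigma = config$sigma, seed = config$seed
  )
  path <- file.path(out_dir, sprintf("simulated_start_%s.csv", config$start))
  write_composition_series(ds, path)
  invisible(list(series = path))
}

#' @rdname pipeline
#' @export
pm_fit_markov <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, n_starts = 8L))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "fit_markov", config)
  if (is.null(config$manifest_path)) {
    abort_validation("fit-markov config needs a `manifest_path`")
  }
  man <- read_series_manifest(config$manifest_path)
  fit <- fit_transition_matrix(man$data, dt = man$dt,
                               n_starts = config$n_starts,
                               seed = config$seed)
  m_path <- file.path(out_dir, "transition_matrix.csv")
  write_transition_matrix(fit$matrix, m_path)
  d_path <- file.path(out_dir, "markov_diagnostics.json")
  jsonlite::write_json(fit$diagnostics, d_path, auto_unbox = TRUE, digits = NA)
  p_path <- file.path(out_dir, "propensity_table.csv")
  readr::write_csv(propensity_table(fit$matrix), p_path)
  invisible(list(matrix = m_path, diagnostics = d_path, propensities = p_path))
}

#' @rdname pipeline
#' @export
pm_fit_qy <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, method = "full_ode_fit",
                                 n_boot = 0L))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "fit_qy", config)
  if (is.null(config$manifest_path)) {
    abort_validation("fit-qy config needs a `manifest_path`")
  }
  man <- read_series_manifest(config$manifest_path)
  cond <- resolve_conditions(config)
  fit <- estimate_quantum_yields(man$data, cond, method = config$method,
                                 n_boot = config$n_boot, seed = config$seed)
  phi_path <- file.path(out_dir, "quantum_yields.csv")
  phi_df <- dplyr::bind_cols(
    tibble::tibble(from = isomer_levels()),
    tibble::as_tibble(as.data.frame(unclass(fit$phi)))
  )
  readr::write_csv(phi_df, phi_path)
  se_path <- file.path(out_dir, "quantum_yield_se.csv")
  se_df <- dplyr::bind_cols(
    tibble::tibble(from = isomer_levels()),
    tibble::as_tibble(as.data.frame(fit$se,
                                    col.names = isomer_levels()))
  )
  names(se_df) <- c("from", isomer_levels())
  readr::write_csv(se_df, se_path)
  invisible(list(phi = phi_path, se = se_path))
}

#' @rdname pipeline
#' @export
pm_thermal <- function(config) {
  config <- config_defaults(load_config(config), list(seed = 20180628L))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "thermal", config)
  if (is.null(config$series_path) || is.null(config$temperature)) {
    abort_validation("thermal config needs `series_path` and `temperature`")
  }
  if (!file.exists(config$series_path)) {
    abort_io(sprintf("no such file: %s", config$series_path))
  }
  df <- readr::read_csv(config$series_path, show_col_types = FALSE,
                        progress = FALSE)
  fit <- fit_reversible_first_order(df, temperature = config$temperature)
  bar_fwd <- eyring_barrier(fit$k_fwd, fit$temperature)
  bar_rev <- eyring_barrier(fit$k_rev, fit$temperature)
  report <- list(
    temperature_K = fit$temperature,
    k_fwd_per_s = fit$k_fwd, k_rev_per_s = fit$k_rev,
    x_eq = fit$x_eq,
    half_life_s = half_life(fit),
    half_life_years = seconds_to_years(half_life(fit)),
    barrier_fwd = list(kJ_per_mol = bar_fwd$delta_G_kJ,
                       kcal_per_mol = bar_fwd$delta_G_kcal),
    barrier_rev = list(kJ_per_mol = bar_rev$delta_G_kJ,
                       kcal_per_mol = bar_rev$delta_G_kcal),
    flags = fit$flags
  )
  path <- file.path(out_dir, "thermal_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(list(report = path))
}

#' @rdname pipeline
#' @export
pm_spectra <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, tol = 0.002))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "spectra", config)
  if (is.null(config$spectra_path)) {
    abort_validation("spectra config needs a `spectra_path`")
  }
  spectra <- read_spectra_series(config$spectra_path)
  iso <- isosbestic_points(spectra, tol = config$tol)
  rank <- two_state_rank_test(spectra)
  report <- list(
    isosbestic_points_nm = iso$wavelength_nm,
    rank_ratio = rank$ratio,
    two_state_consistent = !is.na(rank$ratio) && rank$ratio < 0.01
  )
  path <- file.path(out_dir, "spectra_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  iso_path <- file.path(out_dir, "isosbestic_points.csv")
  readr::write_csv(iso, iso_path)
  invisible(list(report = path, isosbestic = iso_path))
}

#' @rdname pipeline
#' @export
pm_report <- function(config) {
  config <- config_defaults(load_config(config),
                            list(seed = 20180628L, method = "full_ode_fit",
                                 n_boot = 0L, n_starts = 8L))
  out_dir <- ensure_output_dir(config)
  log_run(out_dir, "report", config)
  if (is.null(config$manifest_path)) {
    abort_validation("report config needs a `manifest_path`")
  }
  man <- read_series_manifest(config$manifest_path)
  cond <- resolve_conditions(config)
  markov <- fit_transition_matrix(man$data, dt = man$dt,
                                  n_starts = config$n_starts,
                                  seed = config$seed)
  qy <- estimate_quantum_yields(man$data, cond, method = config$method,
                                n_boot = config$n_boot, seed = config$seed)
  ratio <- quantum_yield_ratio_check(markov$matrix, qy$phi)

  m_path <- file.path(out_dir, "report_transition_matrix.csv")
  write_transition_matrix(markov$matrix, m_path)
  phi_df <- dplyr::bind_cols(
    tibble::tibble(from = isomer_levels()),
    tibble::as_tibble(as.data.frame(unclass(qy$phi)))
  )
  phi_path <- file.path(out_dir, "report_quantum_yields.csv")
  readr::write_csv(phi_df, phi_path)
  prop_path <- file.path(out_dir, "report_propensities.csv")
  readr::write_csv(propensity_table(qy$phi), prop_path)
  bundle <- list(
    seed = config$seed,
    markov_diagnostics = markov$diagnostics,
    qy_diagnostics = qy$diagnostics[c("rss", "n_obs")],
    ratio_consistency = list(
      max_rel_dev = ratio$max_rel_dev, n_skipped = ratio$n_skipped
    )
  )
  b_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, b_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(matrix = m_path, phi = phi_path, propensities = prop_path,
                 bundle = b_path))
}
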