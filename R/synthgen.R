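# Seeded synthetic-data generators emulating the inputs the fitters consume:
# NMR-derived composition time courses with integration noise, reversible
# thermal decays, and two-component absorption-spectra series.

#' Built-in quantum-yield preset
#'
#' Per-channel quantum yields measured for the benzene solution experiment
#' at 405 nm (fractions; source rows to target columns): A converts to B
#' with 9 percent, to C with 31 percent, to D with 0.8 percent; B to A with
#' 0.9, C with 8, D with 9 percent; C to A/B/D with 0.09/0.1/0.07 percent;
#' D to A/B/C with 0.3/0.06/0.01 percent.
#'
#' @param label Preset label; currently `"benzene_27C"`.
#' @return A [quantum_yield_matrix()].
#' @export
#' @examples
#' preset_quantum_yields()["A", "C"]
preset_quantum_yields <- function(label = "benzene_27C") {
  if (!identical(label, "benzene_27C")) {
    abort_validation(sprintf("unknown quantum-yield preset \"%s\"", label))
  }
  phi <- rbind(
    A = c(0,      0.09,   0.31,   0.008),
    B = c(0.009,  0,      0.08,   0.09),
    C = c(0.0009, 0.001,  0,      0.0007),
    D = c(0.003,  0.0006, 0.0001, 0)
  )
  colnames(phi) <- isomer_levels()
  quantum_yield_matrix(phi)
}

#' Built-in irradiation-condition preset
#'
#' A 405 nm continuous irradiation of an NMR-tube-scale sample: photon flux
#' 1e-9 einstein/s, 1 cm path, 0.5 mL volume, 1 mM total chromophore, and
#' equal molar absorption coefficients of 5000 L/mol/cm for all four
#' isomers.
#'
#' @param label Preset label; currently `"benzene_405nm"`.
#' @return A [photo_conditions()] object.
#' @export
preset_photo_conditions <- function(label = "benzene_405nm") {
  if (!identical(label, "benzene_405nm")) {
    abort_validation(sprintf("unknown photo-conditions preset \"%s\"", label))
  }
  photo_conditions(
    wavelength = 405, photon_flux = 1e-9, path_length = 1,
    volume = 5e-4, epsilon = rep(5000, 4), total_conc = 1e-3
  )
}

#' Motion-share condition presets
#'
#' Per-condition propensities of the photoreactions of a given starting
#' isomer to proceed by single-bond rotation, double-bond isomerization, or
#' hula twist, as determined for the solvent/temperature series of
#' experiments. Conditions for which only a two-way ratio was determined
#' carry a zero third share and `partial = TRUE`.
#'
#' @return A tibble with columns `label`, `source`, `sbr`, `dbi`, `ht`,
#'   `partial`, `note`.
#' @export
#' @examples
#' motion_share_presets()
motion_share_presets <- function() {
  tibble::tribble(
    ~label,                ~source, ~sbr, ~dbi, ~ht,  ~partial, ~note,
    "MeOH_d4_A",           "A",     0.40, 0.60, 0,    TRUE,  "polar solvent, SBR vs DBI ratio",
    "toluene_60C_B",       "B",     0.07, 0.56, 0.36, FALSE, "warm toluene (shares renormalized from 7/56/36)",
    "toluene_20C_B",       "B",     0.03, 0.54, 0.43, FALSE, "ambient toluene",
    "toluene_m78C_B",      "B",     0,    0.29, 0.71, TRUE,  "cold liquid toluene",
    "CD2Cl2_27C_B",        "B",     0,    0.45, 0.55, TRUE,  "ambient dichloromethane",
    "CD2Cl2_m80C_B",       "B",     0,    0.24, 0.76, TRUE,  "cold liquid dichloromethane",
    "MeOH_d4_B",           "B",     0,    0.30, 0.70, TRUE,  "polar methanol, HT vs DBI ratio",
    "EPA_m80C_B",          "B",     0,    0.18, 0.82, TRUE,  "cold liquid EPA",
    "toluene_ice_m196C_A", "A",     0.01, 0.83, 0.16, FALSE, "frozen toluene",
    "toluene_ice_m196C_B", "B",     0,    0.68, 0.32, TRUE,  "frozen toluene",
    "CD2Cl2_ice_m196C_A",  "A",     0,    0.99, 0.01, TRUE,  "frozen dichloromethane",
    "CD2Cl2_ice_m196C_B",  "B",     0,    0.93, 0.07, TRUE,  "frozen dichloromethane",
    "EPA_glass_m196C_B",   "B",     0,    0.87, 0.13, TRUE,  "EPA glass"
  ) |>
    dplyr::mutate(
      total = .data$sbr + .data$dbi + .data$ht,
      sbr = .data$sbr / .data$total,
      dbi = .data$dbi / .data$total,
      ht = .data$ht / .data$total
    ) |>
    dplyr::select(-"total")
}

#' Look up one motion-share preset
#'
#' @param label A label from [motion_share_presets()].
#' @return A list with `source` and named `shares` (`SBR`, `DBI`, `HT`).
#' @export
motion_share_preset <- function(label) {
  tab <- motion_share_presets()
  row <- tab[tab$label == label, ]
  if (nrow(row) != 1L) {
    abort_validation(sprintf("unknown motion-share preset \"%s\"", label))
  }
  list(
    source = row$source,
    shares = c(SBR = row$sbr, DBI = row$dbi, HT = row$ht),
    partial = row$partial
  )
}

# Additive Gaussian noise on mole fractions (the NMR integral reading-error
# model), then clip to [0,1] and renormalize so every row stays a valid
# composition.
add_fraction_noise <- function(X, sigma) {
  if (sigma <= 0) return(X)
  noisy <- X + matrix(stats::rnorm(length(X), 0, sigma), nrow = nrow(X))
  t(apply(noisy, 1L, function(x) {
    x <- pmin(pmax(x, 0), 1)
    if (sum(x) <= 0) x <- rep(0.25, length(x))
    x / sum(x)
  }))
}

#' Generate photokinetic composition time courses
#'
#' Emulates the irradiation experiment design: one mole-fraction time course
#' per pure starting isomer, simulated with the full photokinetic forward
#' model and overlaid with NMR-integration noise. Bit-reproducible for a
#' fixed seed.
#'
#' @param phi A [quantum_yield_matrix()] (default the benzene preset).
#' @param cond A [photo_conditions()] object.
#' @param starts Starting isomers, a subset of `A`-`D`.
#' @param times_min Observation times in minutes (shared by all series), or
#'   a named list of per-start time vectors.
#' @param sigma Mole-fraction noise standard deviation (0 = deterministic).
#' @param seed Integer seed.
#' @return A tibble with columns `series`, `start`, `time_min`, `xA` ..
#'   `xD`.
#' @export
#' @examples
#' generate_photokinetic_dataset(starts = "A", times_min = 0:5, sigma = 0)
generate_photokinetic_dataset <- function(phi = preset_quantum_yields(),
                                          cond = preset_photo_conditions(),
                                          starts = isomer_levels(),
                                          times_min = 0:30,
                                          sigma = 0.01,
                                          seed = 20180628L) {
  check_isomer(starts, "starts")
  check_number(sigma, "sigma", nonneg = TRUE)
  if (!is.list(times_min)) {
    times_min <- stats::setNames(rep(list(times_min), length(starts)), starts)
  }
  withr::with_seed(seed, {
    out <- purrr::map(starts, function(s) {
      x0 <- as.numeric(isomer_levels() == s)
      sim <- simulate_photokinetics(x0, phi, cond, times_min[[s]])
      X <- add_fraction_noise(series_as_matrix(sim), sigma)
      tibble::tibble(
        series = paste0("start_", s), start = s, time_min = sim$time_min,
        xA = X[, 1], xB = X[, 2], xC = X[, 3], xD = X[, 4]
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a single-source motion-share dataset
#'
#' Builds the source row of a one-step transition matrix from a motion-share
#' triple and an overall per-step loss probability (off-diagonal entries are
#' `overall_rate * share`, placed at the target state each motion leads to;
#' all other rows are identity), propagates the pure source composition over
#' integer steps, and adds noise. This is the generative model behind the
#' per-condition propensity experiments.
#'
#' @param source Starting isomer label, or a preset label from
#'   [motion_share_presets()] (in which case `shares` is taken from the
#'   preset).
#' @param shares Named triple `c(SBR = , DBI = , HT = )` summing to 1.
#' @param overall_rate Per-step loss probability of the source, in (0, 1).
#' @param steps Integer step grid (minutes at dt = 1).
#' @param sigma Mole-fraction noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with columns `series`, `start`, `time_min`, `xA` ..
#'   `xD`; the generating [transition_matrix()] is attached as attribute
#'   `generator`.
#' @export
#' @examples
#' generate_share_dataset("B", c(SBR = 0, DBI = 0.24, HT = 0.76),
#'                        steps = 0:10, sigma = 0)
generate_share_dataset <- function(source, shares = NULL,
                                   overall_rate = 0.05,
                                   steps = 0:30, sigma = 0,
                                   seed = 20180628L) {
  if (length(source) == 1L && !source %in% isomer_levels()) {
    preset <- motion_share_preset(source)
    source <- preset$source
    if (is.null(shares)) shares <- preset$shares
  }
  check_isomer(source, "source")
  if (is.null(shares) || length(shares) != 3L ||
      is.null(names(shares)) || !setequal(names(shares), c("SBR", "DBI", "HT"))) {
    abort_validation("`shares` must be a named triple over SBR, DBI, HT.")
  }
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    abort_validation("`shares` must be non-negative and sum to 1.")
  }
  if (overall_rate <= 0 || overall_rate >= 1) {
    abort_validation("`overall_rate` must lie strictly between 0 and 1.")
  }
  if (any(abs(steps - round(steps)) > 1e-9) || any(diff(steps) <= 0) ||
      steps[1] != 0) {
    abort_validation("`steps` must be increasing integers starting at 0.")
  }

  M <- diag(4L)
  i <- match(source, isomer_levels())
  for (m in c("SBR", "DBI", "HT")) {
    j <- match(motion_partner(source, m), isomer_levels())
    M[i, j] <- overall_rate * shares[[m]]
  }
  M[i, i] <- 1 - sum(M[i, -i])
  M <- transition_matrix(M, dt = 1)

  x0 <- as.numeric(isomer_levels() == source)
  sim <- propagate_series(M, x0, as.integer(steps))
  X <- withr::with_seed(seed, add_fraction_noise(series_as_matrix(sim), sigma))
  out <- tibble::tibble(
    series = paste0("start_", source), start = source,
    time_min = sim$time_min,
    xA = X[, 1], xB = X[, 2], xC = X[, 3], xD = X[, 4]
  )
  attr(out, "generator") <- M
  out
}

#' Generate a reversible thermal interconversion time course
#'
#' Closed-form reversible first-order decay of a pure starting isomer toward
#' equilibrium, with optional mole-fraction noise.
#'
#' @param k_fwd,k_rev Forward and reverse rate constants, s^-1.
#' @param temperature Temperature, K (recorded in the output attribute).
#' @param times_s Observation times in seconds.
#' @param sigma Noise standard deviation on the fraction.
#' @param seed Integer seed.
#' @param states Length-2 labels of the interconverting pair (start first).
#' @return A tibble with columns `time_s`, `x_start`, `x_other` (attribute
#'   `temperature`).
#' @export
generate_thermal_dataset <- function(k_fwd, k_rev, temperature,
                                     times_s, sigma = 0,
                                     seed = 20180628L,
                                     states = c("A", "B")) {
  check_number(k_fwd, "k_fwd", nonneg = TRUE)
  check_number(k_rev, "k_rev", nonneg = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  check_number(sigma, "sigma", nonneg = TRUE)
  check_isomer(states, "states")
  if (k_fwd + k_rev <= 0) abort_validation("at least one rate must be positive")
  k <- k_fwd + k_rev
  x_eq <- k_rev / k
  x <- x_eq + (1 - x_eq) * exp(-k * times_s)
  if (sigma > 0) {
    x <- withr::with_seed(seed, {
      pmin(pmax(x + stats::rnorm(length(x), 0, sigma), 0), 1)
    })
  }
  out <- tibble::tibble(time_s = times_s, x_start = x, x_other = 1 - x)
  attr(out, "temperature") <- temperature
  attr(out, "states") <- states
  out
}

#' Generate a two-component absorption-spectra series
#'
#' Linear mixtures of two fixed Gaussian-band component spectra along a
#' conversion coordinate, emulating matrix-irradiation UV/vis series with an
#' isosbestic point at the crossing of the two components. An optional third
#' component with its own (incoherent) amplitude trajectory breaks the
#' two-state behaviour.
#'
#' @param fractions Vector of conversion fractions in \[0, 1\], one per
#'   spectrum (at least 3).
#' @param grid Wavelength grid, nm.
#' @param band1,band2 Lists `list(center =, width =, height =)` describing
#'   the component Gaussian bands.
#' @param third Optional third component band plus `amplitudes` vector
#'   (same length as `fractions`).
#' @param sigma Absorbance noise standard deviation.
#' @param seed Integer seed.
#' @return A spectra tibble (`wavelength_nm` plus one column `t<k>` per
#'   spectrum).
#' @export
generate_spectra_dataset <- function(fractions = seq(0, 1, length.out = 8),
                                     grid = seq(300, 550, by = 1),
                                     band1 = list(center = 380, width = 30, height = 1.0),
                                     band2 = list(center = 450, width = 35, height = 0.8),
                                     third = NULL,
                                     sigma = 0,
                                     seed = 20180628L) {
  if (length(fractions) < 3L || any(fractions < 0) || any(fractions > 1)) {
    abort_validation("`fractions` must be at least 3 values in [0, 1].")
  }
  gauss <- function(b) b$height * exp(-(grid - b$center)^2 / (2 * b$width^2))
  s1 <- gauss(band1)
  s2 <- gauss(band2)
  A <- vapply(seq_along(fractions), function(k) {
    spec <- (1 - fractions[k]) * s1 + fractions[k] * s2
    if (!is.null(third)) {
      spec <- spec + third$amplitudes[k] * gauss(third$band)
    }
    spec
  }, numeric(length(grid)))
  if (sigma > 0) {
    A <- withr::with_seed(seed, {
      A + matrix(stats::rnorm(length(A), 0, sigma), nrow = nrow(A))
    })
  }
  out <- tibble::as_tibble(as.data.frame(A))
  names(out) <- paste0("t", seq_along(fractions) - 1L)
  dplyr::bind_cols(tibble::tibble(wavelength_nm = grid), out)
}
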