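#' Irradiation conditions for photokinetic modelling
#'
#' Bundles the experimental parameters of a monochromatic continuous
#' irradiation: photon flux entering the sample, optical path length, sample
#' volume, per-isomer molar absorption coefficients at the irradiation
#' wavelength, and total chromophore concentration.
#'
#' @param wavelength Irradiation wavelength, nm.
#' @param photon_flux Photon flux entering the sample, einstein s^-1.
#' @param path_length Optical path length, cm.
#' @param volume Sample volume, L.
#' @param epsilon Numeric 4-vector (order A, B, C, D) of molar absorption
#'   coefficients at `wavelength`, L mol^-1 cm^-1. Entries may be zero.
#' @param total_conc Total chromophore concentration, mol L^-1.
#' @return An object of class `photo_conditions`.
#' @export
#' @examples
#' photo_conditions(epsilon = rep(5000, 4))
photo_conditions <- function(wavelength = 405,
                             photon_flux = 1e-9,
                             path_length = 1,
                             volume = 5e-4,
                             epsilon = rep(5000, 4),
                             total_conc = 1e-3) {
  check_number(wavelength, "wavelength", positive = TRUE)
  check_number(photon_flux, "photon_flux", positive = TRUE)
  check_number(path_length, "path_length", positive = TRUE)
  check_number(volume, "volume", positive = TRUE)
  check_number(total_conc, "total_conc", positive = TRUE)
  if (!is.numeric(epsilon) || length(epsilon) != 4L ||
      any(!is.finite(epsilon)) || any(epsilon < 0)) {
    abort_validation("`epsilon` must be a non-negative numeric 4-vector.")
  }
  structure(
    list(
      wavelength = wavelength, photon_flux = photon_flux,
      path_length = path_length, volume = volume,
      epsilon = stats::setNames(as.numeric(epsilon), isomer_levels()),
      total_conc = total_conc
    ),
    class = "photo_conditions"
  )
}

#' @export
print.photo_conditions <- function(x, ...) {
  cat(sprintf(
    "<photo_conditions> %g nm, %.3g einstein/s, l = %g cm, V = %g L, c = %g M\n",
    x$wavelength, x$photon_flux, x$path_length, x$volume, x$total_conc
  ))
  cat("  epsilon (L/mol/cm):",
      paste(sprintf("%s=%g", names(x$epsilon), x$epsilon), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-channel photoisomerization quantum-yield matrix
#'
#' Validates a 4x4 matrix of quantum yields where entry (i, j) is the
#' probability that a photon absorbed by isomer i converts it into isomer j
#' (dimensionless fraction). Diagonal entries are zero by convention and row
#' sums may not exceed 1.
#'
#' @param phi 4x4 numeric matrix (order A, B, C, D along both dimensions).
#' @return The validated matrix with class `quantum_yield_matrix`.
#' @export
quantum_yield_matrix <- function(phi) {
  phi <- as.matrix(phi)
  if (!is.numeric(phi) || any(dim(phi) != c(4L, 4L)) || any(!is.finite(phi))) {
    abort_validation("`phi` must be a finite numeric 4x4 matrix.")
  }
  if (any(phi < 0) || any(phi > 1)) {
    abort_validation("quantum yields must lie in [0, 1].")
  }
  if (any(abs(diag(phi)) > 1e-12)) {
    abort_validation("diagonal quantum yields must be zero.")
  }
  diag(phi) <- 0
  if (any(rowSums(phi) > 1 + 1e-9)) {
    abort_validation("quantum-yield row sums may not exceed 1.")
  }
  dimnames(phi) <- list(isomer_levels(), isomer_levels())
  class(phi) <- c("quantum_yield_matrix", class(matrix()))
  phi
}

#' Absorbed-photon rates per isomer
#'
#' Partitions the incident photon flux among the absorbing isomers. With
#' per-isomer absorbances \eqn{A_i = \epsilon_i \, l \, c_{tot} \, x_i} and
#' \eqn{A_{tot} = \sum_i A_i}, isomer i absorbs at rate
#' \deqn{r_i = F \cdot \frac{A_i}{A_{tot}} \left(1 - 10^{-A_{tot}}\right)}
#' einstein per second, where F is the incident flux and
#' \eqn{(1 - 10^{-A_{tot}})} is the photokinetic absorbed-fraction factor.
#' A fully transparent sample (A_tot = 0) absorbs nothing.
#'
#' @param x Composition 4-vector of mole fractions (sums to 1).
#' @param cond A [photo_conditions()] object.
#' @return Named numeric 4-vector of absorbed-photon rates, einstein s^-1.
#' @export
#' @examples
#' cond <- photo_conditions(epsilon = rep(5000, 4))
#' excitation_rates(c(1, 0, 0, 0), cond)
excitation_rates <- function(x, cond) {
  x <- check_composition(x)
  stopifnot(inherits(cond, "photo_conditions"))
  excitation_rates_raw(x, cond)
}

# Internal hot path: no validation, tolerates slightly off-simplex x from the
# integrator (clamped at 0).
excitation_rates_raw <- function(x, cond) {
  x <- pmax(x, 0)
  a <- cond$epsilon * cond$path_length * cond$total_conc * x
  a_tot <- sum(a)
  if (a_tot <= 0) {
    return(stats::setNames(numeric(4L), isomer_levels()))
  }
  cond$photon_flux * (a / a_tot) * (1 - 10^(-a_tot))
}

#' Simulate four-state photokinetics
#'
#' Integrates the continuous-time photokinetic rate equations
#' \deqn{\frac{dn_i}{dt} = \sum_{j \ne i} \left[\Phi_{ji} r_j - \Phi_{ij} r_i\right]}
#' where \eqn{r_i} is the absorbed-photon rate of isomer i from
#' [excitation_rates()] and \eqn{\Phi_{ij}} the per-channel quantum yield.
#' Total moles are conserved; the integration runs in seconds internally with
#' a stiff-safe solver (relative tolerance 1e-8, absolute 1e-10) because the
#' quantum yields of interest span three orders of magnitude.
#'
#' @param x0 Initial composition 4-vector of mole fractions.
#' @param phi A [quantum_yield_matrix()].
#' @param cond A [photo_conditions()] object.
#' @param times_min Monotone increasing vector of observation times in
#'   minutes, starting at 0.
#' @return A tibble with columns `time_min`, `xA`, `xB`, `xC`, `xD`; each row
#'   is clamped to non-negative fractions summing to 1. The attribute
#'   `mass_drift` records the largest deviation of the raw (unrenormalized)
#'   fraction sum from 1 over the trajectory.
#' @export
#' @examples
#' cond <- photo_conditions(epsilon = rep(5000, 4))
#' phi <- quantum_yield_matrix(matrix(0, 4, 4))
#' simulate_photokinetics(c(1, 0, 0, 0), phi, cond, 0:5)
simulate_photokinetics <- function(x0, phi, cond, times_min) {
  x0 <- check_composition(x0, "x0")
  phi <- quantum_yield_matrix(unclass(phi))
  stopifnot(inherits(cond, "photo_conditions"))
  if (!is.numeric(times_min) || length(times_min) < 1L ||
      any(diff(times_min) <= 0) && length(times_min) > 1L) {
    abort_validation("`times_min` must be strictly increasing.")
  }
  if (abs(times_min[1]) > 1e-12) {
    abort_validation("`times_min` must start at 0.")
  }

  n_tot <- cond$total_conc * cond$volume # mol, conserved
  phi_out <- rowSums(phi)
  deriv <- function(t, x, parms) {
    r <- excitation_rates_raw(x, cond)          # einstein/s absorbed per isomer
    dn <- as.vector(crossprod(phi, r)) - phi_out * r # mol/s gain - loss
    list(dn / n_tot)
  }

  times_s <- times_min * 60
  sol <- tryCatch(
    deSolve::lsoda(
      y = x0, times = times_s, func = deriv, parms = NULL,
      rtol = 1e-8, atol = 1e-10
    ),
    error = function(e) {
      abort_convergence(
        sprintf("photokinetic integration failed: %s", conditionMessage(e))
      )
    }
  )
  frac <- sol[, -1, drop = FALSE]
  drift <- max(abs(rowSums(frac) - 1))
  if (drift > 1e-6) {
    abort_convergence(sprintf(
      "photokinetic integration lost mass conservation (drift %.3g)", drift
    ))
  }
  frac <- t(apply(frac, 1L, clamp_composition))
  out <- tibble::tibble(
    time_min = times_min,
    xA = frac[, 1], xB = frac[, 2], xC = frac[, 3], xD = frac[, 4]
  )
  attr(out, "mass_drift") <- drift
  out
}

#' Photostationary state of the four-state photokinetic system
#'
#' Under constant irradiation opposing photoreactions eventually balance;
#' this function finds the composition x* with dx/dt = 0 by integrating the
#' photokinetic equations over successively doubled time chunks until the
#' change per chunk drops below `tol`.
#'
#' @param phi A [quantum_yield_matrix()].
#' @param cond A [photo_conditions()] object.
#' @param x0 Starting composition (default uniform); for reducible systems
#'   the reachable stationary state depends on it.
#' @param tol Convergence tolerance on the max absolute change per chunk.
#' @param max_doublings Iteration cap before a convergence error is raised.
#' @return Named composition 4-vector summing to 1.
#' @export
photostationary_state <- function(phi, cond, x0 = rep(0.25, 4),
                                  tol = 1e-10, max_doublings = 60L) {
  x0 <- check_composition(x0, "x0")
  phi <- quantum_yield_matrix(unclass(phi))
  stopifnot(inherits(cond, "photo_conditions"))
  # Chunk scale: time for the fastest channel to move appreciably.
  per_mol <- cond$photon_flux / (cond$total_conc * cond$volume) # s^-1 scale
  chunk_min <- max(1, 0.1 / (per_mol * max(rowSums(phi), 1e-6))) / 60
  x <- x0
  for (i in seq_len(max_doublings)) {
    sim <- simulate_photokinetics(x, phi, cond, c(0, chunk_min))
    x_new <- as.numeric(sim[2L, c("xA", "xB", "xC", "xD")])
    delta <- max(abs(x_new - x))
    x <- x_new
    if (i >= 3L && delta < tol) {
      return(stats::setNames(x, isomer_levels()))
    }
    chunk_min <- chunk_min * 2
  }
  abort_convergence(
    "photostationary state did not converge within the iteration cap"
  )
}
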