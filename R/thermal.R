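#' Fit reversible first-order interconversion kinetics
#'
#' For a thermal atropisomerization X <-> Y starting from (nearly) pure X,
#' the fraction of X follows
#' \deqn{x(t) = x_{eq} + (x_0 - x_{eq}) e^{-(k_f + k_r) t}}
#' with equilibrium fraction \eqn{x_{eq} = k_r / (k_f + k_r)}. The observed
#' relaxation rate and the equilibrium plateau are fitted by least squares
#' and decomposed into the forward and reverse rate constants.
#'
#' @param series Either a tibble with columns `time_s` and `x_start`
#'   (fraction of the starting isomer), or a four-state composition tibble
#'   (`time_min`, `xA` .. `xD`) in which exactly two states vary (the others
#'   must stay constant within 1 percent).
#' @param temperature Temperature of the measurement, K.
#' @return An object of class `thermal_fit` with rate constants (s^-1),
#'   equilibrium fraction, standard errors, and flags. Non-decaying data
#'   yields a near-zero rate with `wide_uncertainty = TRUE`; data starting
#'   at equilibrium is flagged `unidentifiable`.
#' @export
fit_reversible_first_order <- function(series, temperature) {
  check_number(temperature, "temperature", positive = TRUE)
  series <- as_two_state_series(series)
  t_s <- series$time_s
  x <- series$x_start
  if (length(t_s) < 3L) {
    abort_validation("need at least 3 time points to fit reversible kinetics")
  }

  x0 <- x[1L]
  xeq0 <- mean(tail(x, max(2L, ceiling(length(x) / 5))))
  amp0 <- x0 - xeq0
  k0 <- if (abs(amp0) > 1e-6) {
    mid <- which.min(abs((x - xeq0) / amp0 - exp(-1)))
    1 / max(t_s[mid], diff(range(t_s)) / 10)
  } else {
    1e-3 / max(diff(range(t_s)), 1)
  }

  resid_fn <- function(par) {
    k <- exp(par[1L])
    xeq <- stats::plogis(par[2L])
    xeq + (x0 - xeq) * exp(-k * t_s) - x
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(k0), stats::qlogis(min(max(xeq0, 1e-6), 1 - 1e-6))),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300L,
                                         ftol = 1e-15, ptol = 1e-13)
  )
  k_obs <- exp(fit$par[1L])
  x_eq <- stats::plogis(fit$par[2L])
  k_fwd <- k_obs * (1 - x_eq)
  k_rev <- k_obs * x_eq

  dof <- max(1L, length(x) - 2L)
  sigma2 <- sum(fit$fvec^2) / dof
  cov_par <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se_k <- if (!is.null(cov_par)) k_obs * sqrt(max(cov_par[1L, 1L], 0)) else NA_real_

  total_change <- abs(x0 - x_eq)
  flags <- list(
    unidentifiable = total_change < 0.02,
    wide_uncertainty = total_change < 0.02 ||
      (is.finite(se_k) && se_k > k_obs),
    non_decaying = max(x) - min(x) < 1e-3
  )
  if (flags$unidentifiable) {
    rlang::warn("series starts at (or never leaves) equilibrium; the relaxation rate is unidentifiable",
                class = "photomotion_unidentifiable_warning")
  }
  structure(
    list(
      k_fwd = k_fwd, k_rev = k_rev, k_obs = k_obs, x_eq = x_eq,
      temperature = temperature, se_k_obs = se_k,
      rss = sum(fit$fvec^2), flags = flags,
      data = tibble::tibble(time_s = t_s, x_start = x)
    ),
    class = "thermal_fit"
  )
}

as_two_state_series <- function(series) {
  if (all(c("time_s", "x_start") %in% names(series))) {
    return(tibble::tibble(time_s = series$time_s, x_start = series$x_start))
  }
  df <- validate_composition_frame(series)
  X <- series_as_matrix(df)
  spans <- apply(X, 2L, function(col) max(col) - min(col))
  varying <- which(spans > 0.01)
  if (length(varying) != 2L) {
    abort_validation(
      "expected exactly two states to vary; the others must stay constant within 1%"
    )
  }
  start_idx <- varying[which.max(X[1L, varying])]
  tibble::tibble(time_s = df$time_min * 60, x_start = X[, start_idx])
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf(
    "<thermal_fit> T = %.2f K: k_fwd = %.4g /s, k_rev = %.4g /s, x_eq = %.4f\n",
    x$temperature, x$k_fwd, x$k_rev, x$x_eq
  ))
  if (x$flags$unidentifiable) cat("  [flag] relaxation rate unidentifiable\n")
  invisible(x)
}

#' Eyring barrier from a rate constant
#'
#' Transition-state theory with unit transmission coefficient:
#' \deqn{\Delta G^\ddagger = R T \ln\left(\frac{k_B T}{h\, k}\right)}
#' Constants pinned at CODATA 2018 values. [rate_from_barrier()] is the
#' exact inverse.
#'
#' @param k First-order rate constant, s^-1 (must be positive).
#' @param temperature Temperature, K.
#' @return An object of class `eyring_barrier` with the free energy of
#'   activation in kJ/mol (`delta_G_kJ`) and kcal/mol (`delta_G_kcal`), the
#'   rate, and the temperature.
#' @export
#' @examples
#' eyring_barrier(1e-8, 300.15)
eyring_barrier <- function(k, temperature) {
  check_number(temperature, "temperature", positive = TRUE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort_validation("`k` must be a single positive rate constant (s^-1).")
  }
  dg_J <- .const$R * temperature * log(.const$kB * temperature / (.const$h * k))
  structure(
    list(
      delta_G_kJ = dg_J / 1000,
      delta_G_kcal = dg_J / 1000 * .const$kcal_per_kJ,
      k = k, temperature = temperature
    ),
    class = "eyring_barrier"
  )
}

#' @rdname eyring_barrier
#' @param delta_G_kJ Free energy of activation, kJ/mol.
#' @export
rate_from_barrier <- function(delta_G_kJ, temperature) {
  check_number(temperature, "temperature", positive = TRUE)
  check_number(delta_G_kJ, "delta_G_kJ")
  .const$kB * temperature / .const$h *
    exp(-delta_G_kJ * 1000 / (.const$R * temperature))
}

#' @export
print.eyring_barrier <- function(x, ...) {
  cat(sprintf(
    "<eyring_barrier> dG^ = %.2f kJ/mol (%.2f kcal/mol) at %.2f K (k = %.4g /s)\n",
    x$delta_G_kJ, x$delta_G_kcal, x$temperature, x$k
  ))
  invisible(x)
}

#' Half-life of a first-order process
#'
#' For a one-way decay, t1/2 = ln(2)/k. For the approach to equilibrium of a
#' reversible pair the relevant rate is the relaxation rate k_fwd + k_rev. A
#' zero rate returns `Inf` (the process is not observed).
#'
#' @param x A rate constant (s^-1), a `thermal_fit`, or an `eyring_barrier`.
#' @param ... Unused.
#' @return Half-life in seconds.
#' @export
#' @examples
#' half_life(log(2)) # 1 second
half_life <- function(x, ...) UseMethod("half_life")

#' @export
half_life.default <- function(x, ...) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_validation("`x` must be a single non-negative rate constant.")
  }
  if (x == 0) return(Inf)
  log(2) / x
}

#' @export
half_life.thermal_fit <- function(x, ...) {
  half_life(x$k_fwd + x$k_rev)
}

#' @export
half_life.eyring_barrier <- function(x, ...) {
  half_life(x$k)
}

#' Convert seconds to hours or years
#'
#' Julian year of 365.25 days.
#'
#' @param s Duration in seconds.
#' @return Numeric duration in the target unit.
#' @export
seconds_to_years <- function(s) s / (365.25 * 24 * 3600)

#' @rdname seconds_to_years
#' @export
seconds_to_hours <- function(s) s / 3600

#' Barrier lower bound from non-observation of a reaction
#'
#' If a reaction is not detected after heating for `duration_s` at a given
#' temperature, its rate constant can be at most
#' \eqn{k_{max} = -\ln(1 - f)/\tau} where f is the smallest conversion that
#' would have been detected; the Eyring barrier of that maximal rate is a
#' lower bound on the true barrier. The bound increases with duration
#' (by R T ln 2 per doubling) and decreases as the detection limit loosens.
#'
#' @param duration_s Heating duration, s.
#' @param temperature Temperature, K.
#' @param detection_fraction Smallest detectable converted fraction, in
#'   (0, 1); default 0.05, a conservative NMR integration limit.
#' @return An `eyring_barrier` (the minimum barrier consistent with
#'   non-observation).
#' @export
#' @examples
#' barrier_lower_bound(25 * 3600, 373.15)
barrier_lower_bound <- function(duration_s, temperature,
                                detection_fraction = 0.05) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  if (!is.numeric(detection_fraction) || length(detection_fraction) != 1L ||
      detection_fraction <= 0 || detection_fraction >= 1) {
    abort_validation("`detection_fraction` must lie strictly between 0 and 1.")
  }
  k_max <- -log(1 - detection_fraction) / duration_s
  eyring_barrier(k_max, temperature)
}

#' Eyring regression over several temperatures
#'
#' With rate constants at two or more temperatures, regression of
#' \eqn{\ln(k/T)} on \eqn{1/T} yields the activation enthalpy and entropy:
#' slope \eqn{= -\Delta H^\ddagger / R}, intercept
#' \eqn{= \ln(k_B/h) + \Delta S^\ddagger / R}. With a single temperature the
#' free energy is temperature-independent by assumption and extrapolation
#' uses [eyring_barrier()] directly.
#'
#' @param k Vector of rate constants, s^-1.
#' @param temperature Matching vector of temperatures, K.
#' @return A list with `delta_H_kJ`, `delta_S_J_per_K`, and a function
#'   `rate_at(T)` extrapolating the rate to other temperatures.
#' @export
eyring_regression <- function(k, temperature) {
  if (length(k) != length(temperature) || length(k) < 2L) {
    abort_validation("need rate constants at two or more temperatures")
  }
  if (any(k <= 0) || any(temperature <= 0)) {
    abort_validation("rates and temperatures must be positive")
  }
  fit <- stats::lm(log(k / temperature) ~ I(1 / temperature))
  slope <- coef(fit)[[2L]]
  intercept <- coef(fit)[[1L]]
  dH <- -slope * .const$R
  dS <- (intercept - log(.const$kB / .const$h)) * .const$R
  list(
    delta_H_kJ = dH / 1000,
    delta_S_J_per_K = dS,
    rate_at = function(Tk) {
      .const$kB * Tk / .const$h * exp(-(dH - Tk * dS) / (.const$R * Tk))
    },
    fit = fit
  )
}
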