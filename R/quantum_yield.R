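# Trapezoid cumulative integral of y over t.
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2))
}

#' Early-time analysis window of a photokinetic series
#'
#' At the start of an irradiation of a pure isomer the photoproducts are too
#' dilute to absorb appreciable light, so product formation can be
#' attributed entirely to photons absorbed by the starting material. This
#' returns the maximal initial window over which the photoproducts' share of
#' the total absorbance stays below `threshold`.
#'
#' @param series A composition tibble (`time_min`, `xA` .. `xD`) starting at
#'   least 99 percent pure in one isomer.
#' @param cond A [photo_conditions()] object (supplies the molar absorption
#'   coefficients that weight the absorbance shares).
#' @param threshold Maximum allowed product share of the total absorbance
#'   (default 0.05).
#' @return A list with `start` (the starting isomer), `idx` (integer indices
#'   of the retained rows), `end_time_min` and the per-row `product_share`.
#' @export
early_time_window <- function(series, cond, threshold = 0.05) {
  series <- validate_composition_frame(series)
  stopifnot(inherits(cond, "photo_conditions"))
  check_number(threshold, "threshold", nonneg = TRUE)
  X <- series_as_matrix(series)
  start_idx <- which.max(X[1L, ])
  if (X[1L, start_idx] < 0.99) {
    abort_validation("series must start at least 99% pure in one isomer")
  }
  a <- sweep(X, 2L, cond$epsilon, `*`)
  a_tot <- rowSums(a)
  share <- ifelse(a_tot > 0, 1 - a[, start_idx] / a_tot, 0)
  ok <- share < threshold
  ok[1L] <- TRUE # the pure starting point is always admissible
  n_keep <- if (all(ok)) length(ok) else which(!ok)[1L] - 1L
  list(
    start = isomer_levels()[start_idx],
    idx = seq_len(n_keep),
    end_time_min = series$time_min[n_keep],
    product_share = share
  )
}

# One-interval slope estimate used to initialize the ODE fit: crude but
# always computable, and close to truth when the first interval is short.
initial_phi_guess <- function(aligned_series, cond) {
  n_tot <- cond$total_conc * cond$volume
  phi0 <- matrix(0, 4L, 4L)
  for (s in aligned_series) {
    X <- s$X
    t_s <- s$time_min * 60
    if (nrow(X) < 2L) next
    i <- which.max(X[1L, ])
    r <- excitation_rates_raw(X[1L, ], cond)
    absorbed <- r[i] * (t_s[2L] - t_s[1L]) # einstein in first interval
    if (absorbed <= 0) next
    formed <- pmax(X[2L, ] - X[1L, ], 0) * n_tot
    est <- formed / absorbed
    est[i] <- 0
    est <- pmin(pmax(est, 1e-5), 0.9)
    est[i] <- 0
    if (sum(est) > 0.95) est <- est * 0.95 / sum(est)
    phi0[i, ] <- est
  }
  phi0
}

#' Estimate per-channel photoisomerization quantum yields
#'
#' Two estimators of the quantum-yield matrix from composition time courses
#' recorded under known irradiation conditions, one series per pure starting
#' isomer:
#'
#' * `full_ode_fit` (default): global least-squares fit of the full
#'   photokinetic forward model ([simulate_photokinetics()]) to all series
#'   with the channel quantum yields as free parameters, bounded to
#'   \[0, 1\]. Because the forward model partitions photons among all
#'   absorbers, this mode inherently corrects for photoproduct absorption at
#'   later times.
#' * `early_slope`: for each series, restricts to the [early_time_window()]
#'   and regresses the moles of each product formed on the cumulative
#'   einsteins absorbed by the starting isomer (slope through the origin).
#'   This mirrors the early-time product-identification argument and
#'   systematically underestimates once back-reactions matter.
#'
#' Standard errors come from the Gauss-Newton covariance of the fit; a
#' seeded residual bootstrap is available through `n_boot` for either
#' method.
#'
#' @param data Composition tibble with a `series` column (one series per
#'   starting isomer) or a single series.
#' @param cond A [photo_conditions()] object.
#' @param method `"full_ode_fit"` or `"early_slope"`.
#' @param window_threshold Absorbance-share threshold passed to
#'   [early_time_window()] (early_slope mode).
#' @param n_boot Number of residual-bootstrap draws for uncertainties
#'   (0 = Gauss-Newton errors only).
#' @param seed Seed for the bootstrap draws.
#' @return An object of class `qy_fit` with elements `phi`
#'   (a [quantum_yield_matrix()]), `se`, `method` and `diagnostics`.
#' @export
estimate_quantum_yields <- function(data, cond,
                                    method = c("full_ode_fit", "early_slope"),
                                    window_threshold = 0.05,
                                    n_boot = 0L, seed = 20180628L) {
  method <- match.arg(method)
  data <- validate_composition_frame(data)
  stopifnot(inherits(cond, "photo_conditions"))
  if (!"series" %in% names(data)) data$series <- "series1"
  series_list <- split(data, data$series)
  aligned <- purrr::map(series_list, function(df) {
    list(X = series_as_matrix(df), time_min = df$time_min)
  })

  fitted <- switch(method,
    full_ode_fit = qy_fit_ode(aligned, cond),
    early_slope = qy_fit_slope(aligned, cond, window_threshold)
  )

  if (n_boot > 0L) {
    fitted$se <- qy_bootstrap(fitted, aligned, cond, method,
                              window_threshold, n_boot, seed)
    fitted$diagnostics$n_boot <- n_boot
  }
  structure(
    list(
      phi = quantum_yield_matrix(fitted$phi), se = fitted$se,
      method = method, diagnostics = fitted$diagnostics, data = data
    ),
    class = "qy_fit"
  )
}

qy_fit_ode <- function(aligned, cond) {
  # Free channels: rows of isomers that start some series, or that become
  # populated enough for their own photochemistry to register.
  all_X <- do.call(rbind, purrr::map(aligned, "X"))
  starts <- purrr::map_int(aligned, function(a) which.max(a$X[1L, ]))
  active <- sort(unique(c(starts, which(apply(all_X, 2L, max) > 0.01))))
  channels <- which(
    outer(1:4, 1:4, function(i, j) i != j) &
      matrix(1:4 %in% active, 4L, 4L)
  )

  phi0 <- initial_phi_guess(aligned, cond)
  par0 <- phi0[channels]
  build_phi <- function(par) {
    phi <- matrix(0, 4L, 4L)
    phi[channels] <- pmin(pmax(par, 0), 1)
    phi
  }
  resid_fn <- function(par, obs = NULL) {
    phi_raw <- build_phi(par)
    # keep the forward model defined when the optimizer explores row sums
    # above 1; a penalty residual steers it back into the physical region
    rs <- rowSums(phi_raw)
    over <- pmax(rs - 1, 0)
    phi <- quantum_yield_matrix(phi_raw / pmax(rs, 1))
    res <- unlist(purrr::imap(aligned, function(a, nm) {
      sim <- simulate_photokinetics(a$X[1L, ], phi, cond, a$time_min)
      pred <- as.matrix(sim[, c("xA", "xB", "xC", "xD")])
      target <- if (is.null(obs)) a$X else obs[[nm]]
      as.numeric(pred - target)
    }), use.names = FALSE)
    c(res, 10 * over)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = rep(0, length(par0)), upper = rep(1, length(par0)),
    control = minpack.lm::nls.lm.control(maxiter = 300L,
                                         ftol = 1e-15, ptol = 1e-13)
  )
  phi <- build_phi(fit$par)
  phi <- phi / pmax(rowSums(phi), 1)
  n_res <- length(fit$fvec) - 4L # drop the row-sum penalty slots
  dof <- max(1L, n_res - length(fit$par))
  sigma2 <- sum(fit$fvec^2) / dof
  se_mat <- matrix(NA_real_, 4L, 4L)
  cov_par <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov_par)) se_mat[channels] <- sqrt(pmax(diag(cov_par), 0))
  list(
    phi = phi, se = se_mat,
    diagnostics = list(
      rss = sum(fit$fvec^2), n_obs = n_res, channels = channels,
      convergence = fit$info, message = fit$message
    ),
    resid_fn = resid_fn, channels = channels, par = fit$par
  )
}

qy_fit_slope <- function(aligned, cond, window_threshold) {
  n_tot <- cond$total_conc * cond$volume
  phi <- matrix(0, 4L, 4L)
  se <- matrix(NA_real_, 4L, 4L)
  windows <- list()
  for (a in aligned) {
    df <- tibble::tibble(
      time_min = a$time_min,
      xA = a$X[, 1], xB = a$X[, 2], xC = a$X[, 3], xD = a$X[, 4]
    )
    win <- early_time_window(df, cond, threshold = window_threshold)
    if (length(win$idx) < 3L) {
      abort_validation(sprintf(
        "early-time window for the %s-start series has fewer than 3 points",
        win$start
      ))
    }
    i <- match(win$start, isomer_levels())
    X <- a$X[win$idx, , drop = FALSE]
    t_s <- a$time_min[win$idx] * 60
    rates_i <- apply(X, 1L, function(x) excitation_rates_raw(x, cond)[i])
    absorbed <- cumtrapz(t_s, rates_i) # einstein absorbed by the reactant
    if (max(absorbed) <= 0) next
    for (j in setdiff(1:4, i)) {
      formed <- (X[, j] - X[1L, j]) * n_tot
      slope_fit <- stats::lm(formed ~ 0 + absorbed)
      phi[i, j] <- min(max(coef(slope_fit)[[1]], 0), 1)
      if (coef(slope_fit)[[1]] < 0) {
        rlang::warn(sprintf("negative fitted quantum yield for %s -> %s clamped to 0",
                            isomer_levels()[i], isomer_levels()[j]))
      }
      se[i, j] <- summary(slope_fit)$coefficients[1L, 2L]
    }
    windows[[win$start]] <- win$end_time_min
  }
  list(
    phi = phi, se = se,
    diagnostics = list(windows = windows, threshold = window_threshold)
  )
}

qy_bootstrap <- function(fitted, aligned, cond, method, window_threshold,
                         n_boot, seed) {
  base_phi <- quantum_yield_matrix(fitted$phi)
  sims <- purrr::map(aligned, function(a) {
    sim <- simulate_photokinetics(a$X[1L, ], base_phi, cond, a$time_min)
    as.matrix(sim[, c("xA", "xB", "xC", "xD")])
  })
  resids <- purrr::map2(sims, aligned, function(pred, a) pred - a$X)
  pooled <- unlist(resids)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      boot_data <- purrr::map2(sims, resids, function(pred, res) {
        noisy <- pred + matrix(sample(pooled, length(res), replace = TRUE),
                               nrow = nrow(res))
        noisy <- pmin(pmax(noisy, 0), 1)
        sweep(noisy, 1L, rowSums(noisy), `/`)
      })
      boot_aligned <- purrr::map2(aligned, boot_data, function(a, X) {
        list(X = X, time_min = a$time_min)
      })
      est <- tryCatch(
        switch(method,
          full_ode_fit = qy_fit_ode(boot_aligned, cond)$phi,
          early_slope = qy_fit_slope(boot_aligned, cond, window_threshold)$phi
        ),
        error = function(e) NULL
      )
      est
    })
  })
  draws <- purrr::compact(draws)
  if (length(draws) < 2L) return(fitted$se)
  arr <- simplify2array(draws)
  apply(arr, c(1L, 2L), stats::sd)
}

#' @export
print.qy_fit <- function(x, ...) {
  cat("<qy_fit> quantum-yield matrix (", x$method, ")\n", sep = "")
  print(round(unclass(x$phi) * 100, 3))
  cat("(entries in %, source rows to target columns)\n")
  invisible(x)
}
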