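#' Row-stochastic phototransition matrix
#'
#' Entry (i, j) is the probability that a molecule starting a time step of
#' length `dt` as isomer i ends it as isomer j; the diagonal holds the
#' fraction of the starting isomer remaining after one step.
#'
#' @param M 4x4 numeric matrix with rows summing to 1.
#' @param dt Step duration in minutes (default 1).
#' @return The validated matrix with class `transition_matrix` and attribute
#'   `dt`.
#' @export
transition_matrix <- function(M, dt = 1) {
  M <- as.matrix(M)
  if (!is.numeric(M) || any(dim(M) != c(4L, 4L)) || any(!is.finite(M))) {
    abort_validation("`M` must be a finite numeric 4x4 matrix.")
  }
  if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
    abort_validation("transition probabilities must lie in [0, 1].")
  }
  if (any(abs(rowSums(M) - 1) > 1e-9)) {
    abort_validation("transition-matrix rows must sum to 1.")
  }
  check_number(dt, "dt", positive = TRUE)
  M <- pmin(pmax(M, 0), 1)
  dimnames(M) <- list(isomer_levels(), isomer_levels())
  attr(M, "dt") <- dt
  class(M) <- c("transition_matrix", class(matrix()))
  M
}

#' Propagate a composition through a Markov transition matrix
#'
#' Row-vector convention: the composition after `steps` steps is
#' `x0 %*% M^steps`. Row-stochasticity makes the simplex invariant, so the
#' output sums to 1 by construction.
#'
#' @param M A [transition_matrix()] (or plain row-stochastic 4x4 matrix).
#' @param x0 Composition 4-vector.
#' @param steps Non-negative integer number of steps.
#' @return Named composition 4-vector.
#' @export
#' @examples
#' M <- transition_matrix(diag(4))
#' propagate(M, c(1, 0, 0, 0), 5)
propagate <- function(M, x0, steps) {
  if (!inherits(M, "transition_matrix")) M <- transition_matrix(M)
  x0 <- check_composition(x0, "x0")
  if (!is.numeric(steps) || length(steps) != 1L || steps < 0 ||
      abs(steps - round(steps)) > 1e-9) {
    abort_validation("`steps` must be a non-negative integer.")
  }
  x <- matrix(x0, nrow = 1L)
  Mk <- matpow(unclass(M), as.integer(round(steps)))
  stats::setNames(as.numeric(x %*% Mk), isomer_levels())
}

# Exponentiation by squaring; exact for steps = 0 (identity).
matpow <- function(M, k) {
  out <- diag(nrow(M))
  base <- M
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  out
}

#' Propagate a composition over a grid of steps
#'
#' @inheritParams propagate
#' @param steps Integer vector of step counts (default `0:steps` when a
#'   single value is given to [propagate()]); here a full vector.
#' @return A tibble with columns `time_min`, `xA` .. `xD`.
#' @export
propagate_series <- function(M, x0, steps) {
  if (!inherits(M, "transition_matrix")) M <- transition_matrix(M)
  x0 <- check_composition(x0, "x0")
  dt <- attr(M, "dt")
  rows <- matrix(NA_real_, nrow = length(steps), ncol = 4L)
  x <- x0
  prev <- 0L
  for (i in seq_along(steps)) {
    k <- as.integer(steps[i])
    if (k < prev) abort_validation("`steps` must be non-decreasing.")
    if (k > prev) x <- as.numeric(matrix(x, 1L) %*% matpow(unclass(M), k - prev))
    rows[i, ] <- x
    prev <- k
  }
  tibble::tibble(
    time_min = steps * dt,
    xA = rows[, 1], xB = rows[, 2], xC = rows[, 3], xD = rows[, 4]
  )
}

# --- global fit ------------------------------------------------------------

# Map 3 unconstrained reals onto a simplex row with the diagonal pinned at
# logit 0: exact row-stochasticity at every iterate.
row_from_theta <- function(theta, i) {
  v <- numeric(4L)
  v[-i] <- theta
  e <- exp(v - max(v))
  e / sum(e)
}

series_as_matrix <- function(df) {
  as.matrix(df[, c("xA", "xB", "xC", "xD")])
}

# Interpolate observations onto the integer step grid when times are not
# multiples of dt.
align_series_to_grid <- function(df, dt) {
  steps_raw <- df$time_min / dt
  if (all(abs(steps_raw - round(steps_raw)) < 1e-8)) {
    return(list(steps = as.integer(round(steps_raw)),
                X = series_as_matrix(df), interpolated = FALSE))
  }
  grid <- seq(0L, floor(max(steps_raw)))
  X <- vapply(c("xA", "xB", "xC", "xD"), function(col) {
    stats::approx(steps_raw, df[[col]], xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  X <- t(apply(X, 1L, clamp_composition))
  list(steps = as.integer(grid), X = X, interpolated = TRUE)
}

#' Fit a Markov transition matrix to composition time courses
#'
#' Global least-squares estimation of the row-stochastic one-step transition
#' matrix from one or more mole-fraction time courses (typically one series
#' per pure starting isomer). Each free row is parameterized on the open
#' simplex through a normalized-exponential transform, so every iterate
#' satisfies the constraints exactly; the objective is the sum over all
#' series and time points of squared deviations between observed fractions
#' and the propagated prediction. A seeded multi-start Levenberg-Marquardt
#' search guards against local minima, and off-diagonal entries numerically
#' at zero are projected to exact zero when that does not worsen the fit.
#'
#' Rows of states never populated above `populate_threshold` in any series
#' are unidentifiable from the data; they are returned as identity rows and
#' flagged rather than fitted.
#'
#' @param data A tibble with columns `time_min`, `xA`, `xB`, `xC`, `xD` and
#'   optionally `series` (series identifier; a single series is assumed when
#'   absent). Additional columns are ignored.
#' @param dt Step duration in minutes.
#' @param n_starts Number of seeded optimizer restarts.
#' @param seed Integer seed for the restart draws.
#' @param populate_threshold Mole-fraction level below which a state counts
#'   as never populated.
#' @param ridge Weight of a weak parsimony penalty on the off-diagonal
#'   entries. Composition data cannot distinguish a quiescent pair of states
#'   from a detailed-balance exchange between them (nor a direct channel
#'   from a fast two-step relay through a trace state), so the least-squares
#'   surface has flat valleys; the penalty resolves them toward the
#'   least-churn matrix. The default is far below the data curvature of any
#'   identified entry (noise-free recoveries stay exact to ~1e-6) while
#'   dominating noise-induced tilt along the flat directions; set to 0 for
#'   the plain unpenalized objective.
#' @return An object of class `markov_fit` with elements `matrix` (a
#'   [transition_matrix()]), `diagnostics` (rss, per-series rmsd, flags) and
#'   `data`.
#' @export
#' @examples
#' M <- transition_matrix(rbind(
#'   c(0.95, 0.02, 0.02, 0.01), c(0.01, 0.95, 0.03, 0.01),
#'   c(0.00, 0.01, 0.98, 0.01), c(0.01, 0.01, 0.01, 0.97)
#' ))
#' sim <- propagate_series(M, c(1, 0, 0, 0), 0:20)
#' fit <- fit_transition_matrix(sim)
#' round(fit$matrix, 3)
fit_transition_matrix <- function(data, dt = 1, n_starts = 8L,
                                  seed = 20180628L,
                                  populate_threshold = 0.01,
                                  ridge = 1e-3) {
  data <- validate_composition_frame(data)
  check_number(dt, "dt", positive = TRUE)
  if (!"series" %in% names(data)) data$series <- "series1"
  series_list <- split(data, data$series)
  aligned <- purrr::map(series_list, align_series_to_grid, dt = dt)
  interpolated <- any(purrr::map_lgl(aligned, "interpolated"))
  if (interpolated) {
    rlang::warn(
      "observation times are not integer multiples of dt; interpolated onto the step grid",
      class = "photomotion_interpolation_warning"
    )
  }

  all_X <- do.call(rbind, purrr::map(aligned, "X"))
  populated <- apply(all_X, 2L, max) > populate_threshold
  free_rows <- which(populated)
  fixed_rows <- which(!populated)
  if (all(apply(all_X, 2L, function(col) max(col) - min(col)) < 1e-12)) {
    rlang::warn(
      "all series are constant in time; the transition matrix is only weakly identified",
      class = "photomotion_flat_data_warning"
    )
  }

  build_M <- function(theta) {
    M <- diag(4L)
    for (k in seq_along(free_rows)) {
      i <- free_rows[k]
      M[i, ] <- row_from_theta(theta[(3L * (k - 1L) + 1L):(3L * k)], i)
    }
    M
  }
  residuals_fn <- function(theta) {
    M <- build_M(theta)
    res <- residuals_with_matrix(M, aligned)
    if (ridge > 0) {
      res <- c(res, sqrt(ridge) * M[row(M) != col(M)])
    }
    res
  }

  n_par <- 3L * length(free_rows)
  if (n_par == 0L) {
    M <- transition_matrix(diag(4L), dt = dt)
    return(new_markov_fit(M, residuals_fn(numeric(0)), aligned, fixed_rows,
                          interpolated, data, rss_extra = NULL))
  }

  # Diagonal-dominant default start plus seeded random restarts.
  theta0 <- rep(log(0.02 / 0.94), n_par)
  starts <- withr::with_seed(seed, {
    c(list(theta0), purrr::map(seq_len(max(0L, n_starts - 1L)), function(i) {
      theta0 + stats::rnorm(n_par, 0, 1.5)
    }))
  })
  fits <- purrr::map(starts, function(th) {
    tryCatch(
      minpack.lm::nls.lm(
        par = th, fn = residuals_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 400L, ftol = 1e-15, ptol = 1e-13
        )
      ),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0L) {
    abort_convergence("transition-matrix optimization failed from every start")
  }
  ssr <- purrr::map_dbl(fits, function(f) sum(f$fvec^2))
  best <- fits[[which.min(ssr)]]
  M <- build_M(best$par)

  # Project numerically-zero channels to exact zero if the fit is not hurt.
  M_proj <- M
  for (i in free_rows) {
    small <- M_proj[i, ] < 1e-7 & seq_len(4L) != i
    if (any(small)) {
      M_proj[i, small] <- 0
      M_proj[i, i] <- 1 - sum(M_proj[i, -i])
    }
  }
  res_best <- residuals_with_matrix(M, aligned)
  res_proj <- residuals_with_matrix(M_proj, aligned)
  if (sum(res_proj^2) <= sum(res_best^2) + 1e-12) {
    M <- M_proj
    res_best <- res_proj
  }

  new_markov_fit(transition_matrix(M, dt = dt), res_best, aligned,
                 fixed_rows, interpolated, data,
                 rss_extra = list(n_starts = length(starts),
                                  start_rss = sort(ssr)))
}

residuals_with_matrix <- function(M, aligned) {
  unlist(purrr::map(aligned, function(a) {
    pred <- matrix(NA_real_, nrow = length(a$steps), ncol = 4L)
    x <- a$X[1L, ]
    prev <- 0L
    for (r in seq_along(a$steps)) {
      k <- a$steps[r]
      while (prev < k) {
        x <- as.numeric(x %*% M)
        prev <- prev + 1L
      }
      pred[r, ] <- x
    }
    as.numeric(pred - a$X)
  }), use.names = FALSE)
}

new_markov_fit <- function(M, residuals, aligned, fixed_rows, interpolated,
                           data, rss_extra = NULL) {
  per_series <- purrr::imap_dbl(aligned, function(a, nm) {
    res <- residuals_with_matrix(unclass(M), list(a))
    sqrt(mean(res^2))
  })
  diagnostics <- list(
    rss = sum(residuals^2),
    rmsd = sqrt(mean(residuals^2)),
    per_series_rmsd = per_series,
    identity_rows = isomer_levels()[fixed_rows],
    interpolated = interpolated
  )
  if (!is.null(rss_extra)) diagnostics <- c(diagnostics, rss_extra)
  structure(
    list(matrix = M, diagnostics = diagnostics, data = data),
    class = "markov_fit"
  )
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("<markov_fit> one-step transition matrix (dt =",
      attr(x$matrix, "dt"), "min)\n")
  print(round(unclass(x$matrix), 4))
  cat(sprintf("RSS = %.3g, RMSD = %.3g\n",
              x$diagnostics$rss, x$diagnostics$rmsd))
  if (length(x$diagnostics$identity_rows)) {
    cat("unidentified (identity) rows:",
        paste(x$diagnostics$identity_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Consistency between transition-matrix and quantum-yield ratios
#'
#' Within each source row the off-diagonal transition probabilities should
#' stand in the same ratios as the per-channel quantum yields, because both
#' measure the relative efficiency of the competing photoreaction channels.
#' For every row with at least two channels nonzero in both matrices, all
#' pairwise ratios are compared; the maximum relative deviation and the
#' offending pair are returned. Channel pairs with a zero denominator in
#' either matrix are skipped and counted.
#'
#' @param M A [transition_matrix()] or plain 4x4 row-stochastic matrix.
#' @param phi A [quantum_yield_matrix()] or plain 4x4 matrix.
#' @return A list with `max_rel_dev`, `worst` (tibble row identifying the
#'   source and channel pair), `pairs` (all comparisons) and `n_skipped`.
#' @export
quantum_yield_ratio_check <- function(M, phi) {
  if (!inherits(M, "transition_matrix")) M <- transition_matrix(M)
  phi <- quantum_yield_matrix(unclass(phi))
  M <- unclass(M)
  labels <- isomer_levels()
  rows <- purrr::map(1:4, function(i) {
    targets <- setdiff(1:4, i)
    combos <- utils::combn(targets, 2L)
    purrr::map(seq_len(ncol(combos)), function(c_idx) {
      j <- combos[1L, c_idx]; k <- combos[2L, c_idx]
      skip <- M[i, k] == 0 || phi[i, k] == 0 || M[i, j] == 0 || phi[i, j] == 0
      rel <- if (skip) NA_real_ else {
        abs((M[i, j] / M[i, k]) / (phi[i, j] / phi[i, k]) - 1)
      }
      tibble::tibble(
        source = labels[i], target1 = labels[j], target2 = labels[k],
        skipped = skip, rel_dev = rel
      )
    })
  })
  pairs <- dplyr::bind_rows(purrr::flatten(rows))
  usable <- dplyr::filter(pairs, !.data$skipped)
  if (nrow(usable) == 0L) {
    return(list(max_rel_dev = NA_real_, worst = NULL, pairs = pairs,
                n_skipped = sum(pairs$skipped)))
  }
  worst <- usable[which.max(usable$rel_dev), ]
  list(
    max_rel_dev = worst$rel_dev, worst = worst, pairs = pairs,
    n_skipped = sum(pairs$skipped)
  )
}

#' Partition a source row into motion-type propensities
#'
#' Given the per-target weights of one source isomer (a quantum-yield row or
#' the off-diagonals of a transition-matrix row), computes the fraction of
#' photoreactions proceeding by each motion type. `three_way` normalizes over
#' all three channels; `pairwise` renormalizes over the two motions named in
#' `pair` only (the convention used when only a two-way ratio is reported).
#' Shares are invariant under positive rescaling of the weights.
#'
#' @param weights Named numeric vector of non-negative weights over target
#'   states (names in `A`-`D`), or an unnamed length-4 vector in A-D order
#'   whose source entry is ignored.
#' @param source Source isomer label.
#' @param mode `"three_way"` or `"pairwise"`.
#' @param pair For `mode = "pairwise"`, the two motion types to renormalize
#'   over (default HT vs DBI).
#' @return A tibble with columns `source`, `motion`, `target`, `weight`,
#'   `share`.
#' @export
#' @examples
#' # A-row quantum yields: B 9%, C 31%, D 0.8%
#' propensity_shares(c(B = 0.09, C = 0.31, D = 0.008), "A")
propensity_shares <- function(weights, source,
                              mode = c("three_way", "pairwise"),
                              pair = c("HT", "DBI")) {
  mode <- match.arg(mode)
  check_isomer(source, "source")
  if (length(source) != 1L) abort_validation("`source` must be a single label.")
  if (is.null(names(weights))) {
    if (length(weights) == 4L) {
      names(weights) <- isomer_levels()
      weights <- weights[setdiff(isomer_levels(), source)]
    } else if (length(weights) == 3L) {
      names(weights) <- setdiff(isomer_levels(), source)
    } else {
      abort_validation("unnamed `weights` must have length 3 or 4.")
    }
  }
  weights <- weights[setdiff(isomer_levels(), source)]
  if (any(is.na(weights)) || any(weights < 0)) {
    abort_validation("`weights` must be non-negative for all three targets.")
  }
  motions <- classify_motion(rep(source, 3L), names(weights))
  tab <- tibble::tibble(
    source = rep(source, 3L),
    target = names(weights),
    motion = motions,
    weight = as.numeric(weights)
  )
  if (mode == "pairwise") {
    if (length(pair) != 2L || any(!pair %in% c("SBR", "DBI", "HT")) ||
        pair[1] == pair[2]) {
      abort_validation("`pair` must name two distinct motion types.")
    }
    tab <- dplyr::filter(tab, .data$motion %in% pair)
  }
  total <- sum(tab$weight)
  if (total <= 0) {
    abort_validation("all weights are zero; propensity shares are undefined.")
  }
  dplyr::mutate(tab, share = .data$weight / total)
}

#' Motion-propensity table for every source isomer
#'
#' Applies [propensity_shares()] to each row of a quantum-yield or
#' transition matrix (off-diagonals), skipping sources with no active
#' channel.
#'
#' @param x A [quantum_yield_matrix()], [transition_matrix()] or plain 4x4
#'   matrix of non-negative channel weights.
#' @param mode,pair Passed to [propensity_shares()].
#' @return A tibble with one row per source/motion combination.
#' @export
propensity_table <- function(x, mode = "three_way", pair = c("HT", "DBI")) {
  W <- unclass(as.matrix(x))
  labels <- isomer_levels()
  rows <- purrr::map(1:4, function(i) {
    w <- W[i, -i]
    names(w) <- labels[-i]
    if (sum(w) <= 0) return(NULL)
    propensity_shares(w, labels[i], mode = mode, pair = pair)
  })
  dplyr::bind_rows(purrr::compact(rows))
}
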