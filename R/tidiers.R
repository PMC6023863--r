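# broom-style tidiers for the fitted objects.

#' @export
tidy.markov_fit <- function(x, ...) {
  M <- unclass(x$matrix)
  grid <- tidyr::expand_grid(source = isomer_levels(),
                             target = isomer_levels())
  dplyr::mutate(
    grid,
    probability = as.numeric(t(M)),
    motion = classify_motion(.data$source, .data$target),
    identity_row = .data$source %in% x$diagnostics$identity_rows
  )
}

#' @export
glance.markov_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$diagnostics$rss,
    rmsd = x$diagnostics$rmsd,
    n_series = length(x$diagnostics$per_series_rmsd),
    n_identity_rows = length(x$diagnostics$identity_rows),
    interpolated = x$diagnostics$interpolated,
    dt = attr(x$matrix, "dt")
  )
}

#' @export
tidy.qy_fit <- function(x, ...) {
  phi <- unclass(x$phi)
  grid <- tidyr::expand_grid(source = isomer_levels(),
                             target = isomer_levels())
  out <- dplyr::mutate(
    grid,
    phi = as.numeric(t(phi)),
    se = as.numeric(t(x$se)),
    motion = classify_motion(.data$source, .data$target)
  )
  dplyr::filter(out, .data$source != .data$target)
}

#' @export
glance.qy_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    rss = x$diagnostics$rss %||% NA_real_,
    n_obs = x$diagnostics$n_obs %||% NA_integer_,
    n_boot = x$diagnostics$n_boot %||% 0L
  )
}

#' @export
tidy.thermal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_fwd", "k_rev", "k_obs", "x_eq"),
    estimate = c(x$k_fwd, x$k_rev, x$k_obs, x$x_eq),
    std.error = c(NA_real_, NA_real_, x$se_k_obs, NA_real_)
  )
}

#' @export
glance.thermal_fit <- function(x, ...) {
  tibble::tibble(
    temperature = x$temperature,
    k_obs = x$k_obs,
    half_life_s = half_life(x),
    rss = x$rss,
    unidentifiable = x$flags$unidentifiable
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
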