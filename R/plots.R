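# ggplot2 visualisations. Plots are conveniences; no computation happens
# here that the tabular outputs do not already expose.

#' Plot composition time courses
#'
#' Mole fractions of the four isomers against irradiation time, one line per
#' isomer, facetted by series when several are present.
#'
#' @param data A composition tibble (optionally with a `series` column).
#' @return A ggplot object.
#' @export
plot_composition <- function(data) {
  data <- validate_composition_frame(data)
  long <- tidyr::pivot_longer(
    data, dplyr::all_of(c("xA", "xB", "xC", "xD")),
    names_to = "isomer", values_to = "fraction"
  )
  long$isomer <- sub("^x", "", long$isomer)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_min, y = .data$fraction, colour = .data$isomer
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "irradiation time (min)", y = "mole fraction",
                  colour = "isomer") +
    ggplot2::theme_minimal()
  if ("series" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$series))
  }
  p
}

#' Plot an absorption-spectra series
#'
#' @param spectra Spectra tibble (`wavelength_nm` + time columns).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  validate_spectra_frame(spectra)
  long <- tidyr::pivot_longer(spectra, -"wavelength_nm",
                              names_to = "time", values_to = "absorbance")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$absorbance,
    colour = .data$time, group = .data$time
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance", colour = "spectrum") +
    ggplot2::theme_minimal()
}

matrix_heatmap <- function(tab, fill_col, title) {
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$target, y = .data$source, fill = .data[[fill_col]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3g", .data[[fill_col]])
    ), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(isomer_levels())) +
    ggplot2::labs(title = title, x = "product isomer", y = "starting isomer") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.markov_fit <- function(object, ...) {
  matrix_heatmap(tidy(object), "probability",
                 "one-step phototransition probabilities")
}

#' @export
autoplot.qy_fit <- function(object, ...) {
  tab <- tidy(object)
  matrix_heatmap(tab, "phi", "photoisomerization quantum yields")
}

#' @export
autoplot.thermal_fit <- function(object, ...) {
  t_grid <- seq(min(object$data$time_s), max(object$data$time_s),
                length.out = 200)
  curve <- tibble::tibble(
    time_s = t_grid,
    x_start = object$x_eq +
      (object$data$x_start[1L] - object$x_eq) * exp(-object$k_obs * t_grid)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$x_start)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "fraction of starting isomer") +
    ggplot2::theme_minimal()
}
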