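# Tabular interfaces: composition series as CSV with header
# "time_min,xA,xB,xC,xD", transition matrices as labelled 4x4 CSV, photo
# conditions and manifests as JSON.

validate_composition_frame <- function(data, normalize = TRUE) {
  needed <- c("time_min", "xA", "xB", "xC", "xD")
  if (!is.data.frame(data) || !all(needed %in% names(data))) {
    abort_validation(
      "composition data must have columns time_min, xA, xB, xC, xD"
    )
  }
  data <- tibble::as_tibble(data)
  X <- as.matrix(data[, c("xA", "xB", "xC", "xD")])
  if (any(!is.finite(X)) || any(X < -1e-9)) {
    abort_validation("mole fractions must be finite and non-negative")
  }
  sums <- rowSums(X)
  if (any(abs(sums - 1) > 0.05)) {
    abort_validation("mole-fraction rows must sum to (approximately) 1")
  }
  if (normalize) {
    X <- sweep(pmax(X, 0), 1L, rowSums(pmax(X, 0)), `/`)
    data$xA <- X[, 1]; data$xB <- X[, 2]; data$xC <- X[, 3]; data$xD <- X[, 4]
  }
  grp <- if ("series" %in% names(data)) data$series else rep("s", nrow(data))
  ok_times <- tapply(data$time_min, grp, function(t) all(diff(t) > 0))
  if (any(!ok_times)) {
    abort_validation("`time_min` must be strictly increasing within each series")
  }
  data
}

#' Read / write composition time courses
#'
#' CSV interface with header `time_min,xA,xB,xC,xD` (plus optional `series`
#' and `start` columns). Fractions are renormalized to sum exactly to 1 on
#' read.
#'
#' @param path File path.
#' @return `read_composition_series()` returns a validated tibble;
#'   `write_composition_series()` returns `path` invisibly.
#' @export
read_composition_series <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_composition_frame(df)
}

#' @rdname read_composition_series
#' @param data A composition tibble.
#' @export
write_composition_series <- function(data, path) {
  data <- validate_composition_frame(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Read / write a transition matrix as labelled CSV
#'
#' 4x4 layout with a `from` label column and one column per target state.
#'
#' @param path File path.
#' @param M A [transition_matrix()].
#' @param dt Step duration (minutes) to attach on read.
#' @return The matrix, or `path` invisibly for the writer.
#' @export
write_transition_matrix <- function(M, path) {
  if (!inherits(M, "transition_matrix")) M <- transition_matrix(M)
  df <- tibble::as_tibble(as.data.frame(unclass(M)))
  df <- dplyr::bind_cols(tibble::tibble(from = isomer_levels()), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path, dt = 1) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("from", isomer_levels()) %in% names(df)) || nrow(df) != 4L) {
    abort_io("transition-matrix CSV must have columns from,A,B,C,D and 4 rows")
  }
  M <- as.matrix(df[match(isomer_levels(), df$from), isomer_levels()])
  transition_matrix(M, dt = dt)
}

#' Read / write irradiation conditions as JSON
#'
#' @param path File path.
#' @param cond A [photo_conditions()] object.
#' @return A [photo_conditions()] object, or `path` invisibly.
#' @export
read_photo_conditions <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("wavelength", "photon_flux", "path_length", "volume",
              "epsilon", "total_conc")
  if (!all(needed %in% names(raw))) {
    abort_io(paste("conditions JSON must define:", paste(needed, collapse = ", ")))
  }
  photo_conditions(
    wavelength = raw$wavelength, photon_flux = raw$photon_flux,
    path_length = raw$path_length, volume = raw$volume,
    epsilon = as.numeric(raw$epsilon), total_conc = raw$total_conc
  )
}

#' @rdname read_photo_conditions
#' @export
write_photo_conditions <- function(cond, path) {
  stopifnot(inherits(cond, "photo_conditions"))
  jsonlite::write_json(unclass(cond), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a series manifest
#'
#' A manifest is a JSON object with a `series` array of
#' `{path, start, label}` records (paths relative to the manifest file) and
#' an optional `dt` (minutes). Reading returns the combined composition
#' tibble with `series` and `start` columns, ready for the fitters.
#'
#' @param path Manifest file path.
#' @return A list with `data` (combined tibble) and `dt`.
#' @export
read_series_manifest <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(man$series) || length(man$series) == 0L) {
    abort_io("manifest must list at least one series")
  }
  base <- dirname(path)
  rows <- purrr::imap(man$series, function(s, i) {
    if (is.null(s$path)) abort_io("every manifest series needs a `path`")
    df <- read_composition_series(file.path(base, s$path))
    df$series <- if (!is.null(s$label)) s$label else paste0("series", i)
    if (!is.null(s$start)) {
      check_isomer(s$start, "start")
      df$start <- s$start
    }
    df
  })
  list(
    data = dplyr::bind_rows(rows),
    dt = if (!is.null(man$dt)) man$dt else 1
  )
}

#' Read / write spectra series CSV
#'
#' First column `wavelength_nm`, one absorbance column per time label.
#'
#' @param path File path.
#' @param spectra A spectra tibble.
#' @return The spectra tibble, or `path` invisibly.
#' @export
read_spectra_series <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_spectra_frame(df)
  df
}

#' @rdname read_spectra_series
#' @export
write_spectra_series <- function(spectra, path) {
  validate_spectra_frame(spectra)
  readr::write_csv(spectra, path)
  invisible(path)
}
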