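# Spectra series are tibbles with a `wavelength_nm` column and one column of
# absorbances per recorded time label.

validate_spectra_frame <- function(spectra) {
  if (!is.data.frame(spectra) || !"wavelength_nm" %in% names(spectra)) {
    abort_validation("spectra must be a data frame with a `wavelength_nm` column")
  }
  value_cols <- setdiff(names(spectra), "wavelength_nm")
  if (length(value_cols) < 3L) {
    abort_validation("need at least 3 spectra (time columns) for a series analysis")
  }
  A <- as.matrix(spectra[, value_cols])
  if (any(!is.finite(A)) || any(A < -0.01)) {
    abort_validation("absorbances must be finite and above the -0.01 baseline allowance")
  }
  list(wavelength = spectra$wavelength_nm, A = A, labels = value_cols)
}

#' Detect isosbestic points in an absorption-spectra series
#'
#' During a clean two-state photoconversion every spectrum passes through
#' common crossing wavelengths where the absorbance is time-invariant. A
#' wavelength qualifies when the standard deviation of the absorbance across
#' time is below `tol` while the mean absorbance exceeds `tol` (excluding
#' flat baseline); contiguous qualifying grid points are merged and reported
#' at the wavelength of minimum deviation.
#'
#' When all spectra are identical every non-baseline wavelength qualifies;
#' this degenerate behaviour is intentional (the series carries no
#' conversion information).
#'
#' @param spectra Tibble with `wavelength_nm` plus one absorbance column per
#'   time point (at least 3).
#' @param tol Absorbance tolerance (default 0.002, a typical
#'   spectrophotometer noise floor).
#' @return A tibble with columns `wavelength_nm`, `sd_abs`, `mean_abs`, one
#'   row per merged isosbestic point (possibly empty).
#' @export
isosbestic_points <- function(spectra, tol = 0.002) {
  s <- validate_spectra_frame(spectra)
  check_number(tol, "tol", positive = TRUE)
  sd_abs <- apply(s$A, 1L, stats::sd)
  mean_abs <- rowMeans(s$A)
  hit <- sd_abs < tol & mean_abs > tol
  if (!any(hit)) {
    return(tibble::tibble(wavelength_nm = numeric(0), sd_abs = numeric(0),
                          mean_abs = numeric(0)))
  }
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  rows <- purrr::map_int(keep, function(r) {
    idx <- starts[r]:ends[r]
    idx[which.min(sd_abs[idx])]
  })
  tibble::tibble(
    wavelength_nm = s$wavelength[rows],
    sd_abs = sd_abs[rows],
    mean_abs = mean_abs[rows]
  )
}

#' Rank test for two-state spectral behaviour
#'
#' In a closed two-species system every spectrum is a convex combination of
#' two fixed component spectra, so the time-by-wavelength matrix has rank 1
#' after subtracting the per-wavelength mean. The ratio of the second to the
#' first singular value of the mean-centred matrix therefore measures the
#' evidence for any third component: values below about 0.01 indicate
#' effectively two-component behaviour. The statistic is invariant under
#' wavelength-independent baseline shifts and global intensity rescaling.
#'
#' @param spectra Tibble with `wavelength_nm` plus at least 3 absorbance
#'   columns.
#' @return A list with `ratio` (second/first singular value, `NA` when the
#'   series has zero variance), `singular_values`, and `flagged`.
#' @export
two_state_rank_test <- function(spectra) {
  s <- validate_spectra_frame(spectra)
  M <- t(s$A) # times x wavelengths
  C <- scale(M, center = TRUE, scale = FALSE)
  d <- svd(C, nu = 0, nv = 0)$d
  if (d[1L] < 1e-12) {
    rlang::warn("spectra series has zero variance; rank ratio undefined",
                class = "photomotion_zero_variance_warning")
    return(list(ratio = NA_real_, singular_values = d, flagged = TRUE))
  }
  list(ratio = d[2L] / d[1L], singular_values = d, flagged = FALSE)
}
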