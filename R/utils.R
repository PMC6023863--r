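# Physical constants (CODATA 2018), pinned so that barrier/rate conversions
# are bit-reproducible across platforms.
.const <- list(
  kB = 1.380649e-23,   # J K^-1
  h  = 6.62607015e-34, # J s
  R  = 8.31446,        # J mol^-1 K^-1
  kcal_per_kJ = 1 / 4.184
)

# Classed conditions so callers (and the command-line wrapper) can map error
# families to distinct exit codes.
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "photomotion_validation_error", ...)
}

abort_convergence <- function(msg, ...) {
  rlang::abort(msg, class = "photomotion_convergence_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "photomotion_io_error", ...)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be strictly positive.", name))
  }
  if (nonneg && x < 0) {
    abort_validation(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

# Clamp tiny negative fractions from integrator round-off and renormalize a
# composition vector onto the simplex.
clamp_composition <- function(x, tol = 1e-12) {
  if (any(x < -1e-6)) {
    abort_validation("composition has a substantially negative entry")
  }
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) abort_validation("composition sums to zero")
  x / s
}

check_composition <- function(x, name = "x", tol = 1e-6) {
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x))) {
    abort_validation(sprintf("`%s` must be a finite numeric 4-vector.", name))
  }
  if (any(x < -1e-12)) {
    abort_validation(sprintf("`%s` has a negative mole fraction.", name))
  }
  if (abs(sum(x) - 1) > tol) {
    abort_validation(sprintf("`%s` must sum to 1 (got %.8f).", name, sum(x)))
  }
  invisible(stats::setNames(as.numeric(x), isomer_levels()))
}
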