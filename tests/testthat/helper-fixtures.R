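# Shared generators for the test suite. Everything is built in code under
# fixed seeds; no stored fixtures.

# Random row-stochastic matrix with a dominant diagonal (all rows exercised).
random_stochastic_matrix <- function(seed, off_mass = 0.1) {
  withr::with_seed(seed, {
    M <- diag(4L)
    for (i in 1:4) {
      w <- stats::runif(3L, 0.2, 1)
      M[i, -i] <- off_mass * w / sum(w)
      M[i, i] <- 1 - off_mass
    }
    transition_matrix(M)
  })
}

# Random quantum-yield matrix with strictly positive channels.
random_phi <- function(seed, lo = 1e-3, hi = 0.2) {
  withr::with_seed(seed, {
    phi <- matrix(stats::runif(16L, lo, hi), 4L, 4L)
    diag(phi) <- 0
    rs <- rowSums(phi)
    phi <- phi / pmax(1, max(rs) * 1.01) # keep row sums < 1
    quantum_yield_matrix(phi)
  })
}

# Noise-free multi-series dataset propagated from a known transition matrix,
# one series per pure starting isomer.
markov_dataset <- function(M, starts = isomer_levels(), steps = 0:30) {
  dplyr::bind_rows(lapply(starts, function(s) {
    x0 <- as.numeric(isomer_levels() == s)
    sim <- propagate_series(M, x0, steps)
    dplyr::mutate(sim, series = paste0("start_", s), start = s)
  }))
}

# Matrix exponential through eigendecomposition (independent oracle for the
# exact one-step transition matrix of a linear kinetic system).
expm_eigen <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# Stationary distribution of a continuous-time chain with off-diagonal rates
# proportional to phi (left null vector of the generator).
stationary_from_phi <- function(phi) {
  Q <- unclass(phi)
  diag(Q) <- -rowSums(Q)
  ns <- eigen(t(Q))
  idx <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, idx])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), isomer_levels())
}

benzene_phi <- function() preset_quantum_yields()
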