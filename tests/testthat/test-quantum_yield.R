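test_that("early-time window tracks the product absorbance share", {
  cond <- preset_photo_conditions() # equal epsilons: share = 1 - x_start
  # linear product growth of 1% per minute: share hits 5% at t = 5
  ramp <- tibble::tibble(
    time_min = 0:10,
    xA = 1 - 0.01 * (0:10), xB = 0, xC = 0.01 * (0:10), xD = 0
  )
  win <- early_time_window(ramp, cond, threshold = 0.05)
  expect_equal(win$start, "A")
  expect_equal(win$end_time_min, 4)

  # products that never reach the threshold keep the full series
  slow <- tibble::tibble(
    time_min = 0:10,
    xA = 1 - 0.001 * (0:10), xB = 0.001 * (0:10), xC = 0, xD = 0
  )
  expect_equal(length(early_time_window(slow, cond, 0.05)$idx), 11L)

  # degenerate threshold 0 admits only the pure starting point
  expect_equal(length(early_time_window(ramp, cond, threshold = 0)$idx), 1L)

  impure <- tibble::tibble(time_min = 0:3, xA = 0.9, xB = 0.1, xC = 0, xD = 0)
  expect_error(early_time_window(impure, cond),
               class = "photomotion_validation_error")
})

test_that("zero-conversion series yield an all-zero quantum-yield matrix", {
  cond <- preset_photo_conditions()
  flat <- tibble::tibble(time_min = 0:10, xA = 1, xB = 0, xC = 0, xD = 0)
  fit <- estimate_quantum_yields(flat, cond, method = "early_slope")
  expect_equal(max(unclass(fit$phi)), 0)
})

test_that("early-slope and full ODE fits agree on slow single-channel data", {
  phi_true <- matrix(0, 4, 4); phi_true[1, 3] <- 0.2
  phi_true <- quantum_yield_matrix(phi_true)
  # slow conversion: products stay dilute, both estimators see clean data
  cond <- photo_conditions(photon_flux = 2e-10, epsilon = rep(5000, 4))
  sim <- generate_photokinetic_dataset(phi_true, cond, starts = "A",
                                       times_min = 0:30, sigma = 0)
  slope <- estimate_quantum_yields(sim, cond, method = "early_slope")
  ode <- estimate_quantum_yields(sim, cond, method = "full_ode_fit")
  expect_equal(unclass(ode$phi)[1, 3], 0.2, tolerance = 1e-4)
  expect_equal(unclass(slope$phi)[1, 3], unclass(ode$phi)[1, 3],
               tolerance = 0.02)
})

test_that("generate -> fit round trip recovers arbitrary yield matrices", {
  cond <- preset_photo_conditions()
  for (seed in c(2, 9)) {
    phi_true <- random_phi(seed, lo = 1e-4, hi = 0.4)
    sim <- generate_photokinetic_dataset(phi_true, cond, times_min = 0:25,
                                         sigma = 0)
    fit <- estimate_quantum_yields(sim, cond, method = "full_ode_fit")
    active <- unclass(phi_true) > 0
    rel <- abs(unclass(fit$phi)[active] - unclass(phi_true)[active]) /
      unclass(phi_true)[active]
    expect_lt(max(rel), 0.01)
  }
})

test_that("yield estimates are invariant to flux/time rescaling", {
  phi_true <- benzene_phi()
  cond1 <- preset_photo_conditions()
  cond2 <- photo_conditions(photon_flux = 2 * cond1$photon_flux,
                            epsilon = cond1$epsilon)
  sim1 <- generate_photokinetic_dataset(phi_true, cond1, starts = "A",
                                        times_min = seq(0, 20, 2), sigma = 0)
  sim2 <- generate_photokinetic_dataset(phi_true, cond2, starts = "A",
                                        times_min = seq(0, 10, 1), sigma = 0)
  # doubling the flux and halving the clock produces the same compositions
  expect_equal(sim1$xA, sim2$xA, tolerance = 1e-8)
  f1 <- estimate_quantum_yields(sim1, cond1)
  f2 <- estimate_quantum_yields(sim2, cond2)
  expect_equal(unclass(f1$phi)[1, ], unclass(f2$phi)[1, ], tolerance = 1e-4)
})

test_that("long-window early slopes underestimate when back-reaction bites", {
  phi <- matrix(0, 4, 4); phi[1, 3] <- 0.3; phi[3, 1] <- 0.3
  phi <- quantum_yield_matrix(phi)
  cond <- preset_photo_conditions()
  sim <- generate_photokinetic_dataset(phi, cond, starts = "A",
                                       times_min = 0:30, sigma = 0)
  # threshold 1 keeps the whole series in the "early" window
  slope <- estimate_quantum_yields(sim, cond, method = "early_slope",
                                   window_threshold = 1)
  ode <- estimate_quantum_yields(sim, cond, method = "full_ode_fit")
  expect_lt(unclass(slope$phi)[1, 3], unclass(ode$phi)[1, 3])
  expect_equal(unclass(ode$phi)[1, 3], 0.3, tolerance = 1e-3)
})

test_that("bootstrap uncertainties are reproducible and plausibly scaled", {
  phi_true <- matrix(0, 4, 4); phi_true[1, 3] <- 0.2
  phi_true <- quantum_yield_matrix(phi_true)
  cond <- photo_conditions(photon_flux = 2e-10, epsilon = rep(5000, 4))
  sim <- generate_photokinetic_dataset(phi_true, cond, starts = "A",
                                       times_min = 0:20, sigma = 0.005,
                                       seed = 77)
  # clamping warnings for noise-driven negative slopes are expected here
  f1 <- suppressWarnings(estimate_quantum_yields(sim, cond,
                                                 method = "early_slope",
                                                 n_boot = 25, seed = 5))
  f2 <- suppressWarnings(estimate_quantum_yields(sim, cond,
                                                 method = "early_slope",
                                                 n_boot = 25, seed = 5))
  expect_equal(f1$se, f2$se)
  expect_gt(f1$se[1, 3], 0)
})
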