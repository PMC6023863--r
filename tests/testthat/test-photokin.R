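test_that("excitation rates follow the photon-partition formula", {
  # equal epsilons chosen so A_tot = log10(2): the absorbed fraction is 1/2
  cond <- photo_conditions(
    photon_flux = 2, epsilon = rep(log10(2) / 1e-3, 4), total_conc = 1e-3
  )
  r <- excitation_rates(c(0.5, 0.5, 0, 0), cond)
  expect_equal(unname(r), c(0.5, 0.5, 0, 0), tolerance = 1e-12)

  # transparent sample absorbs nothing
  cond0 <- photo_conditions(epsilon = rep(0, 4))
  expect_equal(unname(excitation_rates(c(1, 0, 0, 0), cond0)), rep(0, 4))

  # total-absorption limit: pure A with huge absorbance takes the full flux
  cond_inf <- photo_conditions(photon_flux = 3, epsilon = c(1e9, 0, 0, 0))
  r_inf <- excitation_rates(c(1, 0, 0, 0), cond_inf)
  expect_equal(r_inf[["A"]], 3, tolerance = 1e-12)
  expect_true(sum(r_inf) <= 3 + 1e-12)

  expect_error(excitation_rates(c(-0.1, 0.5, 0.3, 0.3), cond),
               class = "photomotion_validation_error")
})

test_that("dilute-limit partition agrees with the linearized form to 1.2%", {
  cond <- photo_conditions(epsilon = c(4, 3, 2, 1), total_conc = 1e-3)
  x <- c(0.4, 0.3, 0.2, 0.1)
  a <- cond$epsilon * cond$path_length * cond$total_conc * x
  expect_lte(sum(a), 0.01)
  full <- excitation_rates(x, cond)
  linear <- 2.302585 * cond$photon_flux * a
  expect_equal(unname(full), unname(linear), tolerance = 0.012)
})

test_that("zero quantum yields freeze the composition", {
  cond <- preset_photo_conditions()
  phi0 <- quantum_yield_matrix(matrix(0, 4, 4))
  sim <- simulate_photokinetics(c(0.3, 0.3, 0.2, 0.2), phi0, cond, c(0, 10, 60))
  for (col in c("xA", "xB", "xC", "xD")) {
    expect_equal(sim[[col]], rep(sim[[col]][1], 3), tolerance = 1e-10)
  }
})

test_that("single-channel dilute kinetics match the analytic exponential", {
  # optically thin sample: the decay of the reactant is mono-exponential with
  # rate phi * F * ln(10) * eps * l / V
  phi <- matrix(0, 4, 4); phi[1, 3] <- 0.2
  phi <- quantum_yield_matrix(phi)
  cond <- photo_conditions(
    photon_flux = 1e-9, epsilon = c(10, 0, 0, 0),
    total_conc = 1e-7, volume = 5e-4
  )
  k <- 0.2 * cond$photon_flux * log(10) * 10 * cond$path_length / cond$volume
  times <- seq(0, 30, by = 2)
  sim <- simulate_photokinetics(c(1, 0, 0, 0), phi, cond, times)
  expect_equal(sim$xA, exp(-k * times * 60), tolerance = 1e-6)
})

test_that("mass is conserved to 1e-8 across random channel sets", {
  cond <- preset_photo_conditions()
  for (seed in 1:5) {
    phi <- random_phi(seed)
    x0 <- withr::with_seed(seed, {
      x <- stats::runif(4); x / sum(x)
    })
    sim <- simulate_photokinetics(x0, phi, cond, c(0, 5, 15, 30))
    expect_lt(attr(sim, "mass_drift"), 1e-8)
    expect_equal(rowSums(as.matrix(sim[, -1])), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("raising a channel quantum yield cannot reduce product formation", {
  cond <- photo_conditions(epsilon = rep(10, 4), total_conc = 1e-6)
  build <- function(p) {
    phi <- matrix(0, 4, 4); phi[1, 2] <- p
    quantum_yield_matrix(phi)
  }
  xb <- vapply(c(0.05, 0.1, 0.2, 0.4), function(p) {
    sim <- simulate_photokinetics(c(1, 0, 0, 0), build(p), cond, c(0, 5))
    sim$xB[2]
  }, numeric(1))
  expect_true(all(diff(xb) > 0))
})

test_that("photostationary state handles symmetric and absorbing systems", {
  cond <- preset_photo_conditions()
  # symmetric two-state exchange equilibrates at 50:50
  phi_sym <- matrix(0, 4, 4); phi_sym[1, 3] <- 0.1; phi_sym[3, 1] <- 0.1
  pss <- photostationary_state(quantum_yield_matrix(phi_sym), cond,
                               x0 = c(1, 0, 0, 0))
  expect_equal(unname(pss), c(0.5, 0, 0.5, 0), tolerance = 1e-8)

  # one-way channel drains everything into the absorbing state
  phi_abs <- matrix(0, 4, 4); phi_abs[1, 3] <- 0.1
  pss2 <- photostationary_state(quantum_yield_matrix(phi_abs), cond,
                                x0 = c(1, 0, 0, 0))
  expect_equal(unname(pss2), c(0, 0, 1, 0), tolerance = 1e-8)
})

test_that("photostationary state matches the embedded-chain stationary law", {
  cond <- preset_photo_conditions() # equal epsilons
  phi <- random_phi(42, lo = 0.01, hi = 0.2)
  pss <- photostationary_state(phi, cond)
  expect_equal(unname(pss), unname(stationary_from_phi(phi)), tolerance = 1e-6)

  # a long simulation converges onto the same fixed point
  sim <- simulate_photokinetics(c(1, 0, 0, 0), phi, cond, c(0, 5e4))
  expect_equal(as.numeric(sim[2, -1]), unname(pss), tolerance = 1e-6)
})

test_that("condition and quantum-yield constructors validate inputs", {
  expect_error(photo_conditions(photon_flux = 0),
               class = "photomotion_validation_error")
  expect_error(photo_conditions(epsilon = c(-1, 0, 0, 0)),
               class = "photomotion_validation_error")
  bad <- matrix(0, 4, 4); bad[1, 2] <- 1.2
  expect_error(quantum_yield_matrix(bad),
               class = "photomotion_validation_error")
  bad2 <- matrix(0.4, 4, 4); diag(bad2) <- 0
  expect_error(quantum_yield_matrix(bad2),
               class = "photomotion_validation_error")
})
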