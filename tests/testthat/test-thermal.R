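test_that("reversible first-order rates are recovered from clean decays", {
  ds <- generate_thermal_dataset(1e-5, 1e-5, 355.15,
                                 times_s = seq(0, 2e5, length.out = 40))
  fit <- fit_reversible_first_order(ds, temperature = 355.15)
  expect_equal(fit$k_fwd, 1e-5, tolerance = 1e-3)
  expect_equal(fit$k_rev, 1e-5, tolerance = 1e-3)
  expect_equal(fit$x_eq, 0.5, tolerance = 1e-4)
  expect_false(fit$flags$unidentifiable)
})

test_that("a series starting at equilibrium is flagged unidentifiable", {
  t_s <- seq(0, 1e5, length.out = 20)
  ds <- tibble::tibble(time_s = t_s, x_start = rep(0.5, 20))
  expect_warning(fit <- fit_reversible_first_order(ds, 373.15),
                 class = "photomotion_unidentifiable_warning")
  expect_true(fit$flags$unidentifiable)
  expect_true(fit$flags$wide_uncertainty)
})

test_that("rates survive 1% noise within 5% across seeded replicates", {
  errs <- vapply(1:20, function(s) {
    ds <- generate_thermal_dataset(2e-5, 1e-5, 373.15,
                                   times_s = seq(0, 1.5e5, length.out = 50),
                                   sigma = 0.01, seed = 400 + s)
    fit <- fit_reversible_first_order(ds, 373.15)
    abs(fit$k_obs - 3e-5) / 3e-5
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("four-state input is reduced to its two varying states", {
  k <- 2e-5
  t_min <- seq(0, 2000, length.out = 25)
  xA <- 0.5 + 0.5 * exp(-k * t_min * 60)
  df <- tibble::tibble(time_min = t_min, xA = xA, xB = 1 - xA, xC = 0, xD = 0)
  fit <- fit_reversible_first_order(df, 355.15)
  expect_equal(fit$k_obs, k, tolerance = 1e-3)

  df3 <- df
  df3$xC <- seq(0, 0.2, length.out = 25)
  df3$xA <- df3$xA - df3$xC
  expect_error(fit_reversible_first_order(df3, 355.15),
               class = "photomotion_validation_error")
})

test_that("Eyring conversion round-trips at machine precision", {
  for (k in c(1e-8, 1e-5, 1)) {
    bar <- eyring_barrier(k, 310)
    expect_equal(rate_from_barrier(bar$delta_G_kJ, 310), k,
                 tolerance = 1e-10)
  }
  # attempt-frequency limit: k = kB T / h corresponds to a vanishing barrier
  Tk <- 298.15
  k_att <- 1.380649e-23 * Tk / 6.62607015e-34
  expect_equal(eyring_barrier(k_att, Tk)$delta_G_kJ, 0, tolerance = 1e-12)
  expect_error(eyring_barrier(-1, 300), class = "photomotion_validation_error")
})

test_that("a 1.7-year half-life maps to a ~118.9 kJ/mol barrier at 27 C", {
  k <- log(2) / (1.7 * 365.25 * 24 * 3600)
  bar <- eyring_barrier(k, 300.15)
  expect_equal(bar$delta_G_kJ, 118.9, tolerance = 0.001)
  expect_equal(bar$delta_G_kcal, 28.4, tolerance = 0.002)
  # and back: that barrier reproduces the half-life
  expect_equal(
    seconds_to_years(half_life(rate_from_barrier(bar$delta_G_kJ, 300.15))),
    1.7, tolerance = 1e-6
  )
})

test_that("half-life algebra follows the rate sum rule", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0), Inf)
  ds <- generate_thermal_dataset(1e-5, 1e-5, 355.15,
                                 times_s = seq(0, 2e5, length.out = 30))
  fit <- fit_reversible_first_order(ds, 355.15)
  expect_equal(half_life(fit), log(2) / 2e-5, tolerance = 1e-3)
})

test_that("non-observation after 25 h at 100 C bounds the barrier above 30 kcal/mol", {
  bound <- barrier_lower_bound(25 * 3600, 373.15, detection_fraction = 0.05)
  expect_equal(bound$delta_G_kJ, 136.7, tolerance = 0.001)
  expect_equal(bound$delta_G_kcal, 32.7, tolerance = 0.002)
  expect_gte(bound$delta_G_kcal, 30)
})

test_that("the non-observation bound is monotone and shifts by RT ln 2", {
  durations <- c(1, 5, 25, 100) * 3600
  bounds <- vapply(durations, function(d) {
    barrier_lower_bound(d, 373.15)$delta_G_kJ
  }, numeric(1))
  expect_true(all(diff(bounds) > 0))

  dets <- c(0.01, 0.05, 0.2, 0.6, 0.95)
  bounds_f <- vapply(dets, function(f) {
    barrier_lower_bound(25 * 3600, 373.15, f)$delta_G_kJ
  }, numeric(1))
  expect_true(all(diff(bounds_f) < 0))

  b1 <- barrier_lower_bound(25 * 3600, 373.15)$delta_G_kJ
  b2 <- barrier_lower_bound(50 * 3600, 373.15)$delta_G_kJ
  expect_equal(b2 - b1, 8.31446 * 373.15 * log(2) / 1000, tolerance = 1e-9)

  expect_error(barrier_lower_bound(3600, 373.15, 1),
               class = "photomotion_validation_error")
})

test_that("multi-temperature Eyring regression recovers enthalpy and entropy", {
  dH <- 110e3; dS <- -20 # J/mol, J/mol/K
  temps <- c(345, 360, 375)
  k <- 1.380649e-23 * temps / 6.62607015e-34 *
    exp(-(dH - temps * dS) / (8.31446 * temps))
  reg <- eyring_regression(k, temps)
  expect_equal(reg$delta_H_kJ, 110, tolerance = 1e-6)
  expect_equal(reg$delta_S_J_per_K, -20, tolerance = 1e-6)
  expect_equal(reg$rate_at(300), 1.380649e-23 * 300 / 6.62607015e-34 *
                 exp(-(dH - 300 * dS) / (8.31446 * 300)), tolerance = 1e-9)
})
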