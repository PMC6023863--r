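test_that("propagate agrees with brute-force iteration", {
  M <- transition_matrix(diag(4))
  x0 <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(unname(propagate(M, x0, 9)), x0)

  hop <- diag(4); hop[1, ] <- c(0, 0, 1, 0)
  expect_equal(unname(propagate(transition_matrix(hop), c(1, 0, 0, 0), 1)),
               c(0, 0, 1, 0))

  M2 <- random_stochastic_matrix(7, off_mass = 0.4)
  x <- x0
  for (i in 1:7) x <- as.numeric(x %*% unclass(M2))
  expect_equal(unname(propagate(M2, x0, 7)), x, tolerance = 1e-12)
  expect_equal(sum(propagate(M2, x0, 50)), 1, tolerance = 1e-12)
  expect_error(propagate(M2, x0, -1), class = "photomotion_validation_error")
})

test_that("noise-free recovery of the generating matrix is entrywise exact", {
  M <- random_stochastic_matrix(11)
  data <- markov_dataset(M, steps = 0:30)
  fit <- fit_transition_matrix(data)
  expect_lt(max(abs(unclass(fit$matrix) - unclass(M))), 1e-4)
  expect_lt(fit$diagnostics$rss, 1e-9)
  expect_equal(length(fit$diagnostics$identity_rows), 0L)
})

test_that("unpopulated states give flagged identity rows", {
  # single series from pure A with only the A -> B channel active
  M <- diag(4); M[1, ] <- c(0.9, 0.1, 0, 0)
  data <- markov_dataset(transition_matrix(M), starts = "A", steps = 0:25)
  fit <- fit_transition_matrix(data)
  expect_equal(unclass(fit$matrix)["A", "B"], 0.1, tolerance = 1e-3)
  expect_setequal(fit$diagnostics$identity_rows, c("C", "D"))
  expect_equal(unclass(fit$matrix)["C", ], c(A = 0, B = 0, C = 1, D = 0))
})

test_that("stationary data is fitted by the identity matrix", {
  data <- tibble::tibble(
    time_min = 0:10, xA = 1, xB = 0, xC = 0, xD = 0
  )
  expect_warning(fit <- fit_transition_matrix(data),
                 class = "photomotion_flat_data_warning")
  expect_lt(max(abs(unclass(fit$matrix) - diag(4))), 1e-6)
})

test_that("non-integer observation times are interpolated with a flag", {
  M <- random_stochastic_matrix(3)
  data <- markov_dataset(M, starts = "A", steps = 0:20)
  data$time_min <- data$time_min + c(0, rep(0.4, nrow(data) - 1))
  expect_warning(fit <- fit_transition_matrix(data),
                 class = "photomotion_interpolation_warning")
  expect_true(fit$diagnostics$interpolated)
  # the well-exercised source row is recovered despite the grid interpolation
  expect_lt(max(abs(unclass(fit$matrix)["A", ] - unclass(M)["A", ])), 0.02)
})

test_that("recovery degrades gracefully under mole-fraction noise", {
  M <- random_stochastic_matrix(5, off_mass = 0.15)
  errs <- vapply(1:20, function(rep_seed) {
    noisy <- markov_dataset(M, steps = 0:30)
    X <- as.matrix(noisy[, c("xA", "xB", "xC", "xD")])
    X <- withr::with_seed(1000 + rep_seed, {
      X + matrix(stats::rnorm(length(X), 0, 0.01), nrow = nrow(X))
    })
    X <- t(apply(X, 1, function(x) pmax(x, 0) / sum(pmax(x, 0))))
    noisy[, c("xA", "xB", "xC", "xD")] <- X
    fit <- fit_transition_matrix(noisy, n_starts = 4)
    max(abs(unclass(fit$matrix) - unclass(M)))
  }, numeric(1))
  expect_lt(mean(errs), 0.01)      # on the scale of the noise itself
  expect_lt(max(errs), 3 * 0.03)   # never beyond a 3-sigma-scaled band
})

test_that("transition/quantum-yield ratio consistency is detected", {
  phi <- benzene_phi()
  # small-step embedding: off-diagonals proportional to phi
  M <- unclass(phi) * 0.5
  diag(M) <- 1 - rowSums(M)
  chk <- quantum_yield_ratio_check(transition_matrix(M), phi)
  expect_lt(chk$max_rel_dev, 1e-9)

  # ratios are invariant to the row scale
  M2 <- unclass(phi) * 0.05
  diag(M2) <- 1 - rowSums(M2)
  expect_lt(quantum_yield_ratio_check(transition_matrix(M2), phi)$max_rel_dev,
            1e-9)

  # a 10% perturbation of one entry shows up as a ~10% ratio deviation
  M3 <- M
  M3["A", "B"] <- M3["A", "B"] * 1.1
  M3["A", "A"] <- 1 - sum(M3["A", -1])
  chk3 <- quantum_yield_ratio_check(transition_matrix(M3), phi)
  expect_equal(chk3$max_rel_dev, 0.1, tolerance = 1e-6)
  expect_equal(chk3$worst$source, "A")
})

test_that("propensity shares reproduce direct arithmetic on the yields", {
  # A-row yields: SBR (to B) 9%, DBI (to C) 31%, HT (to D) 0.8%
  shares <- propensity_shares(c(B = 0.09, C = 0.31, D = 0.008), "A")
  get <- function(m) shares$share[shares$motion == m]
  expect_equal(get("SBR"), 0.09 / 0.408, tolerance = 1e-9)
  expect_equal(get("DBI"), 0.31 / 0.408, tolerance = 1e-9)
  expect_equal(get("HT"), 0.008 / 0.408, tolerance = 1e-9)
  expect_equal(round(100 * c(get("SBR"), get("DBI"), get("HT")), 1),
               c(22.1, 76.0, 2.0))

  pair <- propensity_shares(c(B = 0.09, C = 0.31, D = 0.008), "A",
                            mode = "pairwise", pair = c("DBI", "SBR"))
  expect_equal(pair$share[pair$motion == "DBI"], 0.775, tolerance = 1e-9)
  expect_equal(pair$share[pair$motion == "SBR"], 0.225, tolerance = 1e-9)
})

test_that("propensity shares are scale-invariant and reject zero weights", {
  w <- c(B = 0.2, C = 0.5, D = 0.3)
  s1 <- propensity_shares(w, "A")
  s2 <- propensity_shares(w * 137, "A")
  expect_equal(s1$share, s2$share, tolerance = 1e-12)

  one <- propensity_shares(c(B = 1, C = 0, D = 0), "A")
  expect_equal(one$share[one$motion == "SBR"], 1)
  expect_error(propensity_shares(c(B = 0, C = 0, D = 0), "A"),
               class = "photomotion_validation_error")
})

test_that("propensity_table summarizes every active source row", {
  tab <- propensity_table(benzene_phi())
  expect_equal(nrow(tab), 12L)
  sums <- tapply(tab$share, tab$source, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-9)
})
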