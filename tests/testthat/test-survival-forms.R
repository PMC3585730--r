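test_that("survival at zero resource use equals alpha for all forms", {
  for (form in c("exponential", "logistic", "hyperbolic")) {
    sp <- survival_params(form, alpha = 0.99, beta = 0.5)
    expect_equal(survival_fraction(sp, 0), 0.99, tolerance = 1e-12)
  }
  # logistic alpha' relation: lambda(0) = 1/(1 + alpha'), alpha' = 1/a - 1
  ap <- 1 / 0.99 - 1
  expect_equal(ap, 0.01010101, tolerance = 1e-6)
  expect_equal(1 / (1 + ap), 0.99, tolerance = 1e-12)
})

test_that("survival forms match their closed-form expressions", {
  expect_equal(
    survival_fraction(survival_params("hyperbolic", 0.99, 0.1), 10),
    0.99 / 2, tolerance = 1e-12)
  expect_equal(
    survival_fraction(survival_params("exponential", 0.99, 0.5), 2),
    0.99 * exp(-1), tolerance = 1e-12)
  expect_equal(
    survival_fraction(survival_params("logistic", 0.99, 0.2), 5),
    1 / (1 + (1 / 0.99 - 1) * exp(1)), tolerance = 1e-12)
})

test_that("survival is bounded by alpha and strictly decreasing when beta > 0", {
  u <- seq(0, 50, length.out = 200)
  for (form in c("exponential", "logistic", "hyperbolic")) {
    lam <- survival_fraction(survival_params(form, 0.95, 0.3), u)
    expect_true(all(lam > 0 & lam <= 0.95 + 1e-12))
    expect_true(all(diff(lam) < 0))
    flat <- survival_fraction(survival_params(form, 0.95, 0), u)
    expect_equal(flat, rep(0.95, length(u)), tolerance = 1e-12)
  }
})

test_that("literal logistic sign convention increases with resource use", {
  sp <- survival_params("logistic", 0.99, 0.2, logistic_sign = "literal")
  lam <- survival_fraction(sp, c(0, 5, 10))
  expect_equal(lam[1], 0.99, tolerance = 1e-12)
  expect_true(all(diff(lam) > 0))
})

test_that("invalid survival parameters and inputs are rejected by name", {
  expect_error(survival_params("exponential", alpha = 1.2, beta = 0.1),
               "alpha")
  expect_error(survival_params("exponential", alpha = 0, beta = 0.1),
               "alpha")
  expect_error(survival_params("exponential", alpha = 0.9, beta = -1),
               "beta")
  sp <- survival_params("exponential", 0.9, 0.1)
  expect_error(survival_fraction(sp, -1), "u")
})

test_that("Ford-Walford growth has the asymptote as fixed point", {
  g <- growth_params(K = 0.01, phi_inf = 1, phi_0 = 0.01)
  expect_equal(grow_step(1, g), 1, tolerance = 1e-15)
  g0 <- growth_params(K = 0, phi_inf = 1, phi_0 = 0.5)
  expect_equal(grow_step(0.5, g0), 0.5)
  # closed form at the map parameters
  expect_equal(grow_step(0.01, g),
               0.01 * exp(-0.01) + 1 * (1 - exp(-0.01)),
               tolerance = 1e-15)
  expect_equal(grow_step(0.01, g), 0.019850, tolerance = 1e-4)
})

test_that("growth approaches the asymptote monotonically from below", {
  g <- growth_params(K = 0.05, phi_inf = 2, phi_0 = 0.1)
  phi <- 0.1
  traj <- replicate(200, phi <<- grow_step(phi, g))
  expect_true(all(diff(traj) > 0))
  expect_true(all(traj < 2))
  expect_error(grow_step(-1, g), "phi")
  expect_error(growth_params(K = 0.1, phi_inf = 1, phi_0 = 2), "phi_0")
})

test_that("one cohort step composes survival and growth", {
  sp <- survival_params("exponential", 0.99, 0.5)
  g <- growth_params(0.01, 1, 0.01)
  st <- step_cohort(cohort_state(0, 10, 0.01), sp, g)
  expect_equal(st$N, 10 * 0.99 * exp(-0.5 * 0.1), tolerance = 1e-12)
  expect_equal(st$N, 9.4172, tolerance = 1e-4)
  expect_equal(st$phi, 0.019850, tolerance = 1e-4)
  expect_identical(st$t, 1L)
  # empty cohort stays empty
  expect_equal(step_cohort(cohort_state(3, 0, 0.5), sp, g)$N, 0)
  # density-independent limit: N' = alpha * N for any phi
  sp0 <- survival_params("logistic", 0.9, 0)
  g0 <- growth_params(0, 1, 0.7)
  expect_equal(step_cohort(cohort_state(0, 5, 0.7), sp0, g0)$N, 0.9 * 5,
               tolerance = 1e-12)
})

test_that("cohort trajectories iterate the one-step map", {
  sp <- survival_params("exponential", 0.99, 0.5)
  g <- growth_params(0.01, 1, 0.01)
  tr <- simulate_cohort(10, 0.01, sp, g, n_steps = 2)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$N[1], 10)
  expect_equal(tr$phi[1], 0.01)
  # element 1 equals step_cohort of element 0
  st1 <- step_cohort(cohort_state(0, 10, 0.01), sp, g)
  expect_equal(tr$N[2], st1$N, tolerance = 1e-12)
  # hand iteration of the two closed forms
  N1 <- 10 * 0.99 * exp(-0.5 * 10 * 0.01)
  phi1 <- 0.01 * exp(-0.01) + (1 - exp(-0.01))
  N2 <- N1 * 0.99 * exp(-0.5 * N1 * phi1)
  expect_equal(tr$N[3], N2, tolerance = 1e-12)
  expect_equal(N2, 8.4911, tolerance = 1e-4)
  # degenerate and invalid cases
  expect_equal(nrow(simulate_cohort(10, 0.01, sp, g, 0)), 1L)
  expect_error(simulate_cohort(10, 0.01, sp, g, -1), "n_steps")
})

test_that("density never increases and size never shrinks along a trajectory", {
  set.seed(7)
  for (form in c("exponential", "logistic", "hyperbolic")) {
    sp <- survival_params(form, runif(1, 0.8, 1), runif(1, 0, 1))
    g <- growth_params(runif(1, 0, 0.2), 1, runif(1, 0.01, 0.5))
    tr <- simulate_cohort(runif(1, 1, 1e3), g$phi_0, sp, g, 100)
    expect_true(all(diff(tr$N) <= 0))
    expect_true(all(diff(tr$phi) >= 0))
    expect_true(all(tr$phi <= g$phi_inf + 1e-12))
  }
})

test_that("resource-constraint diagnostic flags excess use without clipping", {
  expect_equal(resource_violation(cohort_state(0, 10, 0.1), A = 1),
               list(violated = FALSE, excess = 0))
  expect_equal(resource_violation(cohort_state(0, 20, 0.1), A = 1),
               list(violated = TRUE, excess = 1))
  expect_false(resource_violation(cohort_state(0, 0, 0.1), A = 1)$violated)
  expect_error(resource_violation(cohort_state(0, 1, 0.1), A = 0), "A")
})
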