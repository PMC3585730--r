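test_that("design predictors follow the descriptor definitions", {
  obs <- data.frame(shore = "s1", quadrat = "q1", period = "p1",
                    T_days = 30, N_start = 10, N_end = 8,
                    operc_area = 2, basal_area = 5, dead_cover = 0)
  expect_equal(build_design(obs, "density")$X, 10)
  expect_equal(build_design(obs, "operc_cover")$X, 20)
  expect_equal(build_design(obs, "basal_cover")$X, 50)
  obs$operc_area <- NA_real_
  expect_error(build_design(obs, "operc_cover"), "1 offending row")
})

test_that("noiseless data are recovered exactly for every form x descriptor", {
  for (form in c("exponential", "logistic", "hyperbolic")) {
    for (descriptor in c("density", "basal_cover", "operc_cover")) {
      beta <- if (descriptor == "density") 0.004 else 0.002
      obs <- noiseless_obs(form, descriptor, alpha = 0.95, beta = beta)
      f <- fit_form(obs, form, descriptor)
      expect_equal(f$alpha, 0.95, tolerance = 1e-9)
      expect_equal(unname(f$beta), beta, tolerance = 1e-7)
      expect_true(f$admissible)
      expect_equal(f$adj_r2, 1, tolerance = 1e-9)
    }
  }
})

test_that("linearised OLS agrees with nonlinear least squares on the survival scale", {
  skip_if_not_installed("minpack.lm")
  for (form in c("exponential", "logistic", "hyperbolic")) {
    obs <- noiseless_obs(form, "operc_cover", alpha = 0.95, beta = 0.002)
    f <- fit_form(obs, form, "operc_cover")
    d <- build_design(obs, "operc_cover", form)
    model <- switch(form,
      exponential = S_30 ~ a * exp(-b * X),
      logistic = S_30 ~ 1 / (1 + (1 / a - 1) * exp(b * X)),
      hyperbolic = S_30 ~ a / (1 + b * X))
    nls_fit <- minpack.lm::nlsLM(model, data = d,
                                 start = list(a = 0.9, b = 0.001))
    co <- coef(nls_fit)
    expect_equal(unname(co["a"]), f$alpha, tolerance = 1e-6)
    expect_equal(unname(co["b"]), unname(f$beta), tolerance = 1e-4)
    expect_equal(unname(co["a"]), 0.95, tolerance = 1e-6)
  }
})

test_that("density-independent data yield a near-zero slope", {
  obs <- noiseless_obs("exponential", "density", alpha = 0.9, beta = 0)
  # add tiny jitter so the response is not exactly constant
  tr <- truth_params(form = "exponential", descriptor = "density",
                     alpha = 0.9, beta_live = 0, beta_dead = 0,
                     trait_sdlog = 0, mode = "binomial")
  obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 30),
                          tr, seed = 5)
  f <- fit_form(obs, "exponential", "density")
  expect_equal(unname(f$beta), 0, tolerance = 5e-4)
  expect_equal(f$alpha, 0.9, tolerance = 0.05)
})

test_that("a constant predictor is rejected as rank-deficient", {
  tr <- truth_params(descriptor = "density", settle_min = 50,
                     settle_max = 50, trait_sdlog = 0,
                     mode = "deterministic")
  obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 5,
                                       schedule = data.frame(
                                         period = "p1", T_days = 30)),
                          tr, seed = 1)
  expect_error(fit_form(obs, "logistic", "density"), "density")
})

test_that("adjusted R2 is invariant to affine predictor rescaling", {
  tr <- truth_params()
  obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 30),
                          tr, seed = 9)
  f1 <- fit_form(obs, "logistic", "operc_cover")
  obs2 <- obs
  obs2$operc_area <- obs2$operc_area * 4  # X scaled, beta should shrink 4x
  f2 <- fit_form(obs2, "logistic", "operc_cover")
  expect_equal(f2$adj_r2, f1$adj_r2, tolerance = 1e-12)
  expect_equal(unname(f2$beta) * 4, unname(f1$beta), tolerance = 1e-12)
})

test_that("fitting is invariant to splitting an interval on noiseless data", {
  tr <- truth_params(alpha = 0.95, beta_dead = 0, trait_sdlog = 0,
                     mode = "deterministic")
  des60 <- study_design(n_shores = 1, n_quadrats = 12,
                        schedule = data.frame(period = "p1", T_days = 60))
  des30 <- study_design(n_shores = 1, n_quadrats = 12,
                        schedule = data.frame(period = c("p1a", "p1b"),
                                              T_days = c(30, 30)))
  f60 <- fit_form(simulate_dataset(des60, tr, seed = 4), "logistic",
                  "operc_cover")
  f30 <- fit_form(simulate_dataset(des30, tr, seed = 4), "logistic",
                  "operc_cover")
  expect_equal(f60$alpha, f30$alpha, tolerance = 1e-9)
  expect_equal(unname(f60$beta), unname(f30$beta), tolerance = 1e-7)
})

test_that("residual diagnostics report trend statistics", {
  obs <- noiseless_obs("logistic", "operc_cover")
  f <- fit_form(obs, "logistic", "operc_cover")
  d <- residual_trend(f)
  expect_true(d$available)
  # exactly-zero residuals carry no trend
  z <- recruitr:::residual_trend_core(rep(0, 10), 1:10)
  expect_equal(z$cor_resid_x, 0)
  expect_equal(z$cor_absresid_x, 0)
  # residuals equal to X have rank correlation 1 (independent rank oracle)
  rt <- recruitr:::residual_trend_core(res = f$design$X, X = f$design$X)
  expect_equal(rt$cor_resid_x, 1)
  # quadratic-in-X residual pattern vs direct rank computation
  X <- f$design$X
  res_q <- (X - mean(X))^2
  rt2 <- recruitr:::residual_trend_core(res_q, X)
  expect_equal(rt2$cor_resid_x, cor(rank(res_q), rank(X)),
               tolerance = 1e-12)
  # too few points -> unavailable
  expect_false(recruitr:::residual_trend_core(1:3, 1:3)$available)
})

test_that("Gaussian-OLS AIC follows n ln(RSS/n) + 2k", {
  expect_equal(gaussian_aic(rss = 10, n = 10, n_coef = 1), 4)
  expect_equal(gaussian_aic(5, 20, 3), 20 * log(0.25) + 8)
})

test_that("the extended model nests the plain logistic cover fit", {
  obs <- simulate_dataset(study_design(n_shores = 1), truth_params(),
                          seed = 2)
  f0 <- fit_form(obs, "logistic", "operc_cover")
  fe <- fit_extended(obs, alpha_by_period = FALSE,
                     include_dead_cover = FALSE)
  expect_equal(unname(coef(fe$lm)), unname(coef(f0$lm)), tolerance = 1e-12)
  expect_equal(fe$alpha, f0$alpha, tolerance = 1e-12)
  expect_equal(unname(fe$beta["beta_live"]), unname(f0$beta),
               tolerance = 1e-12)
})

test_that("noiseless extended data are recovered exactly", {
  tr <- truth_params(trait_sdlog = 0, mode = "deterministic")
  obs <- simulate_dataset(study_design(n_shores = 1), tr, seed = 1)
  f <- fit_extended(obs)
  expect_equal(unname(f$alpha), c(0.97, 0.92, 0.92), tolerance = 1e-9)
  expect_equal(unname(f$beta), c(0.04, 0.036), tolerance = 1e-8)
})

test_that("extended-fit validation names the offending structure", {
  obs <- simulate_dataset(study_design(), truth_params(), seed = 1)
  expect_error(fit_extended(obs), "one shore")
  one <- obs[obs$shore == "shore1", ]
  single <- one[one$period == "June-July", ]
  expect_error(fit_extended(single, alpha_by_period = TRUE), "2 census")
  few <- one[one$period != "June-July" | one$quadrat %in% c("q1", "q2"), ]
  expect_error(fit_extended(few, alpha_by_period = TRUE), "June-July")
})

test_that("AIC selection prefers parsimony at equal fit and checks data identity", {
  tr <- truth_params(alpha = 0.95, beta_dead = 0, persistence = 0,
                     trait_sdlog = 0, mode = "deterministic")
  obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 10),
                          tr, seed = 1)
  # dead cover is identically zero: adding its term cannot reduce the
  # RSS, so the parameter penalty decides
  f0 <- fit_extended(obs, FALSE, FALSE)
  f1 <- fit_extended(obs, FALSE, TRUE)
  sel <- select_by_aic(list(f1, f0))
  expect_false(sel$best_spec$include_dead_cover)
  # exact AIC tie: fewer parameters wins
  f_tie <- f1
  f_tie$aic <- f0$aic
  sel2 <- select_by_aic(list(f_tie, f0))
  expect_false(sel2$best_spec$include_dead_cover)
  # candidates on different data are rejected
  obs2 <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 10),
                           tr, seed = 2)
  g1 <- fit_extended(obs2, FALSE, TRUE)
  expect_error(select_by_aic(list(f0, g1)), "different data")
})

test_that("the form x descriptor table carries one adjusted R2 per cell", {
  obs <- simulate_dataset(study_design(n_quadrats = 20), truth_params(),
                          seed = 3)
  tab <- fit_all_forms(obs)
  expect_equal(nrow(tab), 6L)  # 2 shores x 3 descriptors
  expect_true(all(c("exponential", "logistic", "hyperbolic") %in%
                    names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, 3:5]))))
})
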