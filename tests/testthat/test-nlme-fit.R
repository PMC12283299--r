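test_that("individual parameters compose multiplicatively", {
  th <- typical_params()
  cov <- data.frame(SEX = 1, ALT = 34.85, AGE = 70)

  # identity with no effects and eta = 0
  expect_equal(unclass(individual_parameters(th, list(), cov)), unclass(th))

  # continuous effect at its reference value is a unit multiplier
  ef <- covariate_effect("V1", "ALT", "continuous_power", theta_j = 0.7,
                         reference = 34.85)
  expect_equal(unclass(individual_parameters(th, list(ef), cov)), unclass(th))

  # categorical 1.3-fold sex effect on CL
  sex <- covariate_effect("CL", "SEX", "categorical_exponent", theta_j = 1.3)
  p <- individual_parameters(th, list(sex), cov)
  expect_equal(p[["CL"]], 58.2 * 1.3, tolerance = 1e-12)
  p0 <- individual_parameters(th, list(sex), data.frame(SEX = 0))
  expect_equal(p0[["CL"]], 58.2, tolerance = 1e-12)

  # eta acts as exp(eta)
  p <- individual_parameters(th, list(), cov, eta = c(CL = 0.2, Q = -0.1))
  expect_equal(p[["CL"]], 58.2 * exp(0.2), tolerance = 1e-12)
  expect_equal(p[["Q"]], 20 * exp(-0.1), tolerance = 1e-12)

  expect_error(individual_parameters(
    th, list(covariate_effect("CL", "ALT", "continuous_power", 0.5, 34.85)),
    data.frame(ALT = -2)), "non-positive")
})

test_that("chi-square OFV thresholds match the quantile oracle", {
  expect_equal(round(chi2_threshold(0.05, 1), 2), 3.84)
  expect_equal(chi2_threshold(0.001, 1), 10.82757, tolerance = 1e-5)
  expect_equal(chi2_threshold(0.5, 1), 0.4549364, tolerance = 1e-6)
  expect_error(chi2_threshold(0, 1), "alpha")
  expect_error(chi2_threshold(0.05, 0), "df")
})

test_that("objective collapses to the closed form without random effects", {
  th <- typical_params()
  reg <- constant_infusion(12, 8)
  times <- c(8, 9, 10)
  f <- conc_profile(th, reg, times)
  y <- f * c(1.1, 0.9, 1.05)
  ds <- toy_dataset(y, times)
  spec <- model_spec("proportional", iiv = character(0))
  got <- foce_objective(ds, spec, th, omega = numeric(), sigma_prop = 0.25)
  v <- (0.25 * f)^2
  expect_equal(got$ofv, sum(log(v) + (y - f)^2 / v), tolerance = 1e-10)
})

test_that("FOCE-I matches adaptive-quadrature -2LL in the linear-Gaussian regime", {
  th <- typical_params()
  reg <- constant_infusion(12, 8)
  times <- c(8, 8.5, 9, 10)
  set.seed(31)
  y <- conc_profile(th, reg, times) + rnorm(4, 0, 10)
  ds <- toy_dataset(y, times)
  spec <- model_spec("combined", iiv = "CL")
  omega <- 3e-4  # small enough that exp(eta) is linear over the eta mass
  got <- foce_objective(ds, spec, th, c(CL = omega), sigma_prop = 1e-10,
                        sigma_add = 10)
  oracle <- quad_m2ll_oracle(y, times, reg, th, omega, 10)
  expect_equal(got$ofv, oracle, tolerance = 1e-6)
})

test_that("objective is additive over subjects and exchangeable in IDs", {
  pop <- default_population_model()
  ds <- simulate_cohort(pop, n = 6, seed = 32)
  spec <- model_spec("proportional")
  th <- typical_params()
  om <- pop$omega
  one <- foce_objective(ds, spec, th, om, 0.25)

  # duplicate every subject under new IDs: OFV doubles
  dup <- ds
  dup$ID <- dup$ID + 100
  both <- rbind(ds, dup)
  two <- foce_objective(both, spec, th, om, 0.25)
  expect_equal(two$ofv, 2 * one$ofv, tolerance = 1e-6)

  # permuting subject IDs leaves OFV unchanged
  perm <- ds
  perm$ID <- c(6, 5, 4, 3, 2, 1)[perm$ID]
  expect_equal(foce_objective(perm, spec, th, om, 0.25)$ofv, one$ofv,
               tolerance = 1e-8)
})

test_that("OFV shifts by the known constant under unit rescaling", {
  # scaling DV, dose rates and the additive sigma by s multiplies every
  # residual variance by s^2: OFV changes by exactly n * log(s^2)
  pop <- population_model(typical_params(), omega = c(CL = 0.3),
                          sigma_prop = 0, sigma_add = 5)
  ds <- simulate_cohort(pop, n = 5, seed = 33)
  spec <- model_spec("combined", iiv = "CL")
  th <- typical_params()
  base <- foce_objective(ds, spec, th, c(CL = 0.3), 1e-10, 5)
  s <- 10
  ds2 <- ds
  ds2$DV <- ds2$DV * s
  ds2$RATE <- ds2$RATE * s
  ds2$AMT <- ds2$AMT * s
  scaled <- foce_objective(ds2, spec, th, c(CL = 0.3), 1e-10, 5 * s)
  n <- sum(ds$EVID == 0 & ds$BLQ == 0)
  expect_equal(scaled$ofv - base$ofv, n * log(s^2), tolerance = 1e-6)
  expect_equal(scaled$ebe, base$ebe, tolerance = 1e-4)
})

test_that("fitting noise-free data recovers the generating clearance", {
  pop <- population_model(typical_params(),
                          omega = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                          sigma_prop = 0.03, sigma_add = 0)
  ds <- simulate_cohort(pop, n = 32, seed = 34, dropout = 0)
  spec <- model_spec("proportional", iiv = character(0))
  fit <- fit_model(ds, spec, compute_se = FALSE)
  expect_true(fit$converged)
  expect_lte(fit$ofv, fit$ofv_init)
  expect_lt(abs(fit$theta[["CL"]] - 58.2) / 58.2, 0.05)
  expect_lt(abs(fit$theta[["V1"]] - 25.5) / 25.5, 0.15)
})

test_that("stepwise screening honours its thresholds and tie rules", {
  eff <- covariate_effect("CL", "SEX", "categorical_exponent", theta_j = 1.5)
  pop <- population_model(typical_params(), omega = c(CL = 0.25),
                          sigma_prop = 0.2, effects = list(eff))
  ds <- simulate_cohort(pop, n = 48, seed = 35)
  base <- model_spec("proportional", iiv = "CL")
  cands <- list(covariate_effect("CL", "SEX", "categorical_exponent"))

  # threshold = Inf returns the base model, with the tested delta on record
  res_inf <- forward_selection(ds, base, cands, threshold = Inf)
  expect_equal(length(res_inf$spec$effects), 0)
  expect_equal(nrow(res_inf$trace), 1)

  # a strong simulated effect is picked up at the 3.84 threshold, and the
  # selection decision is exactly the likelihood-ratio rule
  res <- forward_selection(ds, base, cands, threshold = 3.84)
  delta <- res$trace$delta_ofv[1]
  expect_equal(length(res$spec$effects) == 1, delta >= 3.84)
  expect_true(length(res$spec$effects) == 1)
  expect_gt(res$fit$effects[[1]]$theta_j, 1)

  # backward elimination of an empty model is a no-op
  back0 <- backward_elimination(ds, base, threshold = 10.82)
  expect_equal(length(back0$spec$effects), 0)

  # the same effect survives backward elimination iff its removal costs
  # at least the backward threshold
  full <- base
  full$effects <- cands
  back <- backward_elimination(ds, full, threshold = 10.82)
  kept <- length(back$spec$effects) == 1
  expect_equal(kept, delta >= 10.82)
})
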