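# A fit-shaped object at known parameter values, bypassing estimation, so
# diagnostics can be exercised under the exact generating model.
fit_at_truth <- function(ds, pop, spec = model_spec("proportional")) {
  subjects <- remipopk:::dataset_to_subjects(ds)
  obj <- remipopk:::foce_objective_subjects(subjects, spec, pop$theta,
                                            pop$omega[spec$iiv],
                                            pop$sigma_prop, pop$sigma_add)
  structure(list(
    theta = pop$theta, effects = pop$effects, omega = pop$omega,
    sigma_prop = pop$sigma_prop, sigma_add = pop$sigma_add,
    ofv = obj$ofv, ebe = obj$ebe, converged = TRUE, spec = spec,
    subjects = subjects, data = ds
  ), class = "popk_fit")
}

test_that("CWRES are calibrated under the generating model", {
  pop <- default_population_model()
  ds <- simulate_cohort(pop, n = 32, seed = 41)
  fit <- fit_at_truth(ds, pop)
  cw <- cwres(fit)
  expect_equal(nrow(cw), sum(ds$EVID == 0 & ds$BLQ == 0))
  frac <- mean(abs(cw$CWRES) <= 2)
  expect_gt(frac, 0.88)
  expect_lt(abs(mean(cw$CWRES)), 0.3)
})

test_that("CWRES without random effects reduce to scaled residuals", {
  pop <- population_model(typical_params(), omega = c(CL = 0),
                          sigma_prop = 0.2)
  ds <- simulate_cohort(pop, n = 4, seed = 42)
  spec <- model_spec("proportional", iiv = character(0))
  fit <- fit_at_truth(ds, pop, spec)
  cw <- cwres(fit)
  expect_equal(cw$PRED, cw$IPRED, tolerance = 1e-10)
  # with a diagonal C the residual is (y - PRED) / sd(y)
  expect_equal(cw$CWRES, (cw$DV - cw$PRED) / (0.2 * cw$IPRED),
               tolerance = 1e-6)
})

test_that("shrinking residual error drives IPRED to the observations", {
  pop <- default_population_model()
  mis <- function(sig) {
    pop$sigma_prop <- sig
    ds <- simulate_cohort(pop, n = 4, seed = 43)
    cw <- cwres(fit_at_truth(ds, pop))
    max(abs(cw$IPRED - cw$DV) / cw$DV)
  }
  m_small <- mis(0.005)
  expect_lt(m_small, mis(0.05))  # conditional modes track data ever closer
  expect_lt(m_small, 0.1)
})

test_that("bootstrap resamples subjects and brackets the point estimate", {
  pop <- population_model(typical_params(), omega = c(CL = 0.3),
                          sigma_prop = 0.25)
  ds <- simulate_cohort(pop, n = 32, seed = 44)
  spec <- model_spec("proportional", iiv = "CL")
  fit <- fit_model(ds, spec, compute_se = FALSE)
  bs <- bootstrap(ds, spec, n_reps = 40, seed = 45,
                  init = list(theta = fit$theta, omega = fit$omega,
                              sigma_prop = fit$sigma_prop))
  expect_gte(bs$n_converged, 20)
  s <- bs$summary
  expect_true(all(s$lo <= s$median & s$median <= s$hi))
  cl_med <- s$median[s$parameter == "CL"]
  expect_lt(abs(cl_med - fit$theta[["CL"]]) / fit$theta[["CL"]], 0.10)

  # seed reproducibility
  bs2 <- bootstrap(ds, spec, n_reps = 10, seed = 46,
                   init = list(theta = fit$theta, omega = fit$omega,
                               sigma_prop = fit$sigma_prop))
  bs3 <- bootstrap(ds, spec, n_reps = 10, seed = 46,
                   init = list(theta = fit$theta, omega = fit$omega,
                               sigma_prop = fit$sigma_prop))
  expect_identical(bs2$summary, bs3$summary)
})

test_that("bootstrap of a cloned-subject dataset collapses its intervals", {
  pop <- population_model(typical_params(), omega = c(CL = 0.3),
                          sigma_prop = 0.25)
  one <- simulate_cohort(pop, n = 1, seed = 47)
  clones <- do.call(rbind, lapply(1:8, function(j) {
    s <- one
    s$ID <- j
    s
  }))
  spec <- model_spec("proportional", iiv = "CL")
  fit <- fit_model(clones, spec, compute_se = FALSE)
  bs <- bootstrap(clones, spec, n_reps = 5, seed = 48,
                  init = list(theta = fit$theta, omega = fit$omega,
                              sigma_prop = fit$sigma_prop))
  s <- bs$summary
  width <- (s$hi - s$lo)[s$parameter == "CL"]
  expect_lt(width / fit$theta[["CL"]], 1e-6)
})

test_that("prediction correction is the identity when PRED is flat in a bin", {
  # identical design and covariate-free model: PRED constant within bins
  pop <- population_model(typical_params(), omega = c(CL = 0.3),
                          sigma_prop = 0.2)
  regs <- replicate(8, constant_infusion(6, 8), simplify = FALSE)
  cv <- sample_covariates(8, seed = 49)
  ds <- simulate_cohort(pop, n = 8, seed = 49, dropout = 0,
                        covariates = cv, regimens = regs)
  fit <- fit_at_truth(ds, pop, model_spec("proportional", iiv = "CL"))
  v <- pcvpc(fit, n_sim = 50, seed = 50)
  obs <- ds$DV[ds$EVID == 0]
  expect_equal(sort(v$pc_obs$pc), sort(obs), tolerance = 1e-10)
})

test_that("a misspecified model is flagged by the pcVPC bands", {
  pop <- default_population_model()
  ds <- simulate_cohort(pop, n = 32, seed = 51)
  wrong <- pop
  wrong$theta <- pk_params(58.2 / 2, 25.5, 20, 34.5)  # halved clearance
  fit <- fit_at_truth(ds, wrong)
  v <- pcvpc(fit, n_sim = 200, seed = 52)
  outside <- with(v$bins, obs_p50 < p50_lo | obs_p50 > p50_hi)
  expect_true(any(outside))
})

test_that("npde edge cases follow the pde clipping and centering rules", {
  pop <- population_model(typical_params(), omega = c(CL = 0.3),
                          sigma_prop = 0.2)
  ds <- simulate_cohort(pop, n = 1, seed = 53, dropout = 0)
  obs_rows <- which(ds$EVID == 0)
  ds1 <- ds[c(which(ds$EVID == 1), obs_rows[1]), ]  # single observation
  K <- 400

  # observation far below every simulation: pde clipped at 1/(2K)
  low <- ds1
  low$DV[low$EVID == 0] <- 1e-6
  fit <- fit_at_truth(low, pop, model_spec("proportional", iiv = "CL"))
  nd <- npde(fit, n_sim = K, seed = 54)
  expect_equal(nd$npde, qnorm(1 / (2 * K)), tolerance = 1e-10)

  # observation at the center of its predictive distribution: npde near 0
  mid <- ds1
  fit0 <- fit_at_truth(mid, pop, model_spec("proportional", iiv = "CL"))
  set.seed(530)
  sims <- replicate(20000,
    remipopk:::simulate_subject_obs(fit0, fit0$subjects)[[1]][1])
  mid$DV[mid$EVID == 0] <- median(sims)
  fitm <- fit_at_truth(mid, pop, model_spec("proportional", iiv = "CL"))
  ndm <- npde(fitm, n_sim = 2000, seed = 55)
  expect_lt(abs(ndm$npde), 0.1)
})

test_that("npde summaries are calibrated and seed-stable", {
  pop <- default_population_model()
  ds <- simulate_cohort(pop, n = 32, seed = 56)
  fit <- fit_at_truth(ds, pop)
  nd <- npde(fit, n_sim = 400, seed = 57)
  expect_lt(abs(nd$mean), 0.2)
  expect_gt(nd$variance, 0.75)
  expect_lt(nd$variance, 1.25)
  expect_true(all(c(nd$p_wilcoxon, nd$p_variance, nd$p_shapiro) >= 0))
  expect_equal(nd$p_global,
               min(1, 3 * min(nd$p_wilcoxon, nd$p_variance, nd$p_shapiro)))
  nd2 <- npde(fit, n_sim = 400, seed = 57)
  expect_identical(nd$npde, nd2$npde)
})
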