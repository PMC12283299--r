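fit_sigma <- function(fit) c(prop = fit$sigma_prop, add = fit$sigma_add)

# Simulate one replicate of the observation vectors of `subjects` under the
# fitted model: fresh eta per subject, residual error optional. Negative
# draws are redrawn, matching the generating process.
simulate_subject_obs <- function(fit, subjects, residual = TRUE) {
  m <- length(fit$spec$iiv)
  lapply(subjects, function(s) {
    eta <- if (m > 0) {
      stats::setNames(stats::rnorm(m, 0, fit$omega[fit$spec$iiv]), fit$spec$iiv)
    } else numeric()
    p <- individual_parameters(fit$theta, fit$effects, s$covariates, eta)
    f <- conc_profile(p, regimen(s$starts, s$rates, s$durations), s$times)
    if (!residual) return(f)
    y <- rep(-1, length(f))
    bad <- rep(TRUE, length(f))
    while (any(bad)) {
      k <- sum(bad)
      y[bad] <- f[bad] * (1 + stats::rnorm(k, 0, fit$sigma_prop)) +
        stats::rnorm(k, 0, fit$sigma_add)
      bad <- y < 0
    }
    y
  })
}

#' Residual diagnostics: PRED, IPRED and CWRES
#'
#' Population predictions (`eta = 0`), individual predictions (at the
#' empirical Bayes estimates) and conditional weighted residuals under the
#' FOCE linearization: `CWRES = C^{-1/2} (y - (f(ebe) - G ebe))` with
#' `C = G Omega G' + V(ebe)`. For a well-specified model CWRES are
#' approximately standard normal, so about 95% fall within +/- 2.
#'
#' @param fit A `popk_fit`.
#' @return Data frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`.
#' @export
cwres <- function(fit) {
  spec <- fit$spec
  m <- length(spec$iiv)
  om <- if (m > 0) fit$omega[spec$iiv] else numeric()
  out <- lapply(seq_along(fit$subjects), function(i) {
    s <- fit$subjects[[i]]
    tp <- individual_parameters(fit$theta, fit$effects, s$covariates)
    pred <- conc_profile(tp, regimen(s$starts, s$rates, s$durations), s$times)
    eta_i <- if (m > 0) fit$ebe[i, ] else numeric()
    det <- .foce_subject_cpp(s[c("y", "times", "starts", "rates", "durations")],
                             unclass(tp), iiv_index(spec$iiv), om^2,
                             fit$sigma_prop, fit$sigma_add,
                             as.numeric(eta_i))
    C <- det$C
    ev <- eigen(C, symmetric = TRUE)
    if (any(ev$values <= 0)) {
      stop("singular FOCE covariance for subject ", s$id)
    }
    Cinv_half <- ev$vectors %*% diag(1 / sqrt(ev$values), nrow = length(ev$values)) %*%
      t(ev$vectors)
    mu <- det$f - if (m > 0) det$G %*% as.numeric(eta_i) else 0
    cw <- as.numeric(Cinv_half %*% (s$y - mu))
    data.frame(ID = s$id, TIME = s$times, DV = s$y, PRED = pred,
               IPRED = as.numeric(det$f), CWRES = cw)
  })
  do.call(rbind, out)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects (not rows) with replacement, refits each replicate
#' starting from the original estimates, and summarizes converged replicates
#' by the median and the 2.5th/97.5th percentiles per parameter.
#'
#' @param ds Dataset data frame.
#' @param spec A [model_spec()].
#' @param n_reps Number of bootstrap replicates (1000 in the study).
#' @param seed Integer seed.
#' @param init Starting values; when `NULL` the original dataset is fitted
#'   first and its estimates used.
#' @return A `popk_bootstrap` list: `summary` (median, lo, hi per
#'   parameter), `estimates` (replicate x parameter matrix), `n_converged`.
#' @export
bootstrap <- function(ds, spec = model_spec(), n_reps = 1000, seed = NULL,
                      init = NULL) {
  ids <- unique(ds$ID)
  if (length(ids) < 2) stop("bootstrap needs >= 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    base_fit <- fit_model(ds, spec, compute_se = FALSE)
    init <- list(theta = base_fit$theta, omega = base_fit$omega,
                 sigma_prop = base_fit$sigma_prop,
                 sigma_add = max(base_fit$sigma_add, 0.1),
                 effect_theta = vapply(base_fit$effects, `[[`, numeric(1),
                                       "theta_j"))
  }
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    take <- sample(ids, length(ids), replace = TRUE)
    boot_ds <- do.call(rbind, lapply(seq_along(take), function(j) {
      sub <- ds[ds$ID == take[j], ]
      sub$ID <- j
      sub
    }))
    f <- fit_quiet(boot_ds, spec, init)
    reps[[r]] <- if (!is.null(f) && f$converged) f$estimates else NULL
  }
  est <- do.call(rbind, reps)
  if (is.null(est) || nrow(est) < n_reps / 2) {
    stop("more than half of the bootstrap replicates failed to converge")
  }
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, stats::median),
    lo = apply(est, 2, stats::quantile, 0.025),
    hi = apply(est, 2, stats::quantile, 0.975)
  )
  structure(list(summary = summ, estimates = est,
                 n_converged = nrow(est), n_reps = n_reps),
            class = "popk_bootstrap")
}

nominal_bin_of <- function(subjects) {
  offs <- post_cessation_offsets()
  unlist(lapply(subjects, function(s) {
    t_end <- max(s$starts + s$durations)
    vapply(s$times, function(t) which.min(abs((t - t_end) - offs)), integer(1))
  }))
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets on the observed design, corrects
#' observed and simulated values by `median(PRED in bin) / PRED_ij`
#' (prediction correction), and summarizes the 5th/50th/95th percentiles of
#' the observations against 95% confidence bands of the same percentiles
#' across simulations. Bins default to the eight nominal post-cessation
#' sampling times. Also reports the fraction of observations inside the
#' simulated 90% prediction interval of their bin.
#'
#' @param fit A `popk_fit`.
#' @param n_sim Number of simulated replicates.
#' @param seed Integer seed.
#' @return A `popk_vpc` list: `bins` (per-bin observed percentiles and
#'   simulated bands), `coverage90` (fraction inside the 90% interval),
#'   `pc_obs` (per-observation prediction-corrected values and bins).
#' @export
pcvpc <- function(fit, n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- fit$subjects
  pred <- unlist(lapply(subjects, function(s) {
    tp <- individual_parameters(fit$theta, fit$effects, s$covariates)
    conc_profile(tp, regimen(s$starts, s$rates, s$durations), s$times)
  }))
  obs <- unlist(lapply(subjects, `[[`, "y"))
  bin <- nominal_bin_of(subjects)
  used_bins <- sort(unique(bin))
  med_pred <- stats::ave(pred, bin, FUN = stats::median)
  pc_obs <- obs * med_pred / pred

  qs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(used_bins, function(b) {
    stats::quantile(pc_obs[bin == b], qs, names = FALSE)
  }, numeric(3)))

  sim_pct <- array(NA_real_, c(n_sim, length(used_bins), 3))
  pooled <- vector("list", length(used_bins))
  for (r in seq_len(n_sim)) {
    ysim <- unlist(simulate_subject_obs(fit, subjects))
    pc_sim <- ysim * med_pred / pred
    for (bi in seq_along(used_bins)) {
      v <- pc_sim[bin == used_bins[bi]]
      sim_pct[r, bi, ] <- stats::quantile(v, qs, names = FALSE)
      pooled[[bi]] <- c(pooled[[bi]], v)
    }
  }
  bands <- do.call(rbind, lapply(seq_along(used_bins), function(bi) {
    data.frame(
      bin = used_bins[bi],
      offset_min = round(post_cessation_offsets()[used_bins[bi]] * 60),
      n_obs = sum(bin == used_bins[bi]),
      obs_p5 = obs_pct[bi, 1], obs_p50 = obs_pct[bi, 2], obs_p95 = obs_pct[bi, 3],
      p5_lo = stats::quantile(sim_pct[, bi, 1], 0.025, names = FALSE),
      p5_hi = stats::quantile(sim_pct[, bi, 1], 0.975, names = FALSE),
      p50_lo = stats::quantile(sim_pct[, bi, 2], 0.025, names = FALSE),
      p50_hi = stats::quantile(sim_pct[, bi, 2], 0.975, names = FALSE),
      p95_lo = stats::quantile(sim_pct[, bi, 3], 0.025, names = FALSE),
      p95_hi = stats::quantile(sim_pct[, bi, 3], 0.975, names = FALSE)
    )
  }))
  inside <- logical(length(pc_obs))
  for (bi in seq_along(used_bins)) {
    lims <- stats::quantile(pooled[[bi]], c(0.05, 0.95), names = FALSE)
    sel <- bin == used_bins[bi]
    inside[sel] <- pc_obs[sel] >= lims[1] & pc_obs[sel] <= lims[2]
  }
  structure(list(bins = bands, coverage90 = mean(inside),
                 pc_obs = data.frame(bin = bin, pc = pc_obs)),
            class = "popk_vpc")
}

#' Normalized prediction distribution errors
#'
#' For each subject, `n_sim` replicate observation vectors are simulated
#' under the model; observed and simulated vectors are decorrelated with the
#' empirical mean and lower Cholesky factor of the simulation covariance;
#' the prediction discrepancy `pde` is the fraction of decorrelated
#' simulations below the decorrelated observation (ties counted half),
#' clipped to `[1/(2K), 1 - 1/(2K)]`; `npde = qnorm(pde)`. Under a correct
#' model npde is standard normal: tested by Wilcoxon signed rank (mean 0),
#' a chi-square scale test of `sum(npde^2)` against its df (the variance
#' test), and Shapiro-Wilk (normality), with a Bonferroni global test.
#'
#' @param fit A `popk_fit`.
#' @param n_sim Number of simulated replicates (K).
#' @param seed Integer seed.
#' @return A `popk_npde` list: `npde` per observation, `mean`, `variance`,
#'   `p_wilcoxon`, `p_variance`, `p_shapiro`, `p_global`.
#' @export
npde <- function(fit, n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- fit$subjects
  K <- n_sim
  sims <- vector("list", length(subjects))  # per subject: n_i x K
  for (i in seq_along(subjects)) {
    sims[[i]] <- matrix(NA_real_, length(subjects[[i]]$y), K)
  }
  for (r in seq_len(K)) {
    ys <- simulate_subject_obs(fit, subjects)
    for (i in seq_along(subjects)) sims[[i]][, r] <- ys[[i]]
  }
  npde_all <- unlist(lapply(seq_along(subjects), function(i) {
    y <- subjects[[i]]$y
    S <- sims[[i]]
    mu <- rowMeans(S)
    V <- stats::cov(t(S))
    L <- tryCatch(t(chol(V)), error = function(e) {
      t(chol(V + diag(1e-8 * mean(diag(V)), nrow(V))))
    })
    ystar <- forwardsolve(L, y - mu)
    sstar <- forwardsolve(L, S - mu)
    pde <- vapply(seq_along(y), function(j) {
      (sum(sstar[j, ] < ystar[j]) + 0.5 * sum(sstar[j, ] == ystar[j])) / K
    }, numeric(1))
    pde <- pmin(pmax(pde, 1 / (2 * K)), 1 - 1 / (2 * K))
    stats::qnorm(pde)
  }))
  n <- length(npde_all)
  p_w <- stats::wilcox.test(npde_all, mu = 0, exact = FALSE)$p.value
  s2 <- sum(npde_all^2)
  p_v <- min(1, 2 * min(stats::pchisq(s2, n),
                        stats::pchisq(s2, n, lower.tail = FALSE)))
  p_s <- if (n >= 3 && n <= 5000) {
    stats::shapiro.test(npde_all)$p.value
  } else NA_real_
  structure(list(npde = npde_all, mean = mean(npde_all),
                 variance = if (n > 1) stats::var(npde_all) else NA_real_,
                 p_wilcoxon = p_w, p_variance = p_v, p_shapiro = p_s,
                 p_global = min(1, 3 * min(c(p_w, p_v, p_s), na.rm = TRUE))),
            class = "popk_npde")
}
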