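#' Covariate effect term
#'
#' A single multiplicative covariate-parameter relation. Continuous
#' covariates enter as a power of the covariate normalized by its reference
#' (median) value, `theta_tv * (COV / reference)^theta_j`; categorical
#' (0/1) covariates enter as `theta_tv * theta_j^COV` with `theta_j > 0`.
#'
#' @param parameter One of `"CL"`, `"V1"`, `"Q"`, `"V2"`.
#' @param covariate Covariate column name (e.g. `"SEX"`, `"ALT"`).
#' @param form `"continuous_power"` or `"categorical_exponent"`.
#' @param theta_j Effect estimate (exponent for continuous, fold-change for
#'   categorical; categorical must be > 0).
#' @param reference Reference (median) covariate value; continuous only.
#' @return A `covariate_effect` list.
#' @export
covariate_effect <- function(parameter, covariate,
                             form = c("continuous_power", "categorical_exponent"),
                             theta_j = if (match.arg(form) == "categorical_exponent") 1 else 0,
                             reference = NULL) {
  form <- match.arg(form)
  stopifnot(parameter %in% c("CL", "V1", "Q", "V2"))
  if (form == "continuous_power" && is.null(reference)) {
    stop("continuous_power effects need a reference (median) value")
  }
  if (form == "categorical_exponent" && theta_j <= 0) {
    stop("categorical theta_j must be > 0")
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta_j = theta_j, reference = reference),
            class = "covariate_effect")
}

#' Individual parameters from typical values, covariates and random effects
#'
#' Multiplicative composition: `typical * covariate multipliers * exp(eta)`.
#' Parameters without inter-individual variability use `eta = 0`.
#'
#' @param theta A [pk_params()] of typical values.
#' @param effects List of [covariate_effect()] terms.
#' @param cov One-row data frame of the subject's covariates.
#' @param eta Named numeric vector of random effects (missing names are 0).
#' @return A [pk_params()] for the individual.
#' @export
individual_parameters <- function(theta, effects, cov, eta = numeric()) {
  theta <- as_pk_params(theta)
  p <- unclass(theta)
  for (ef in effects) {
    x <- cov[[ef$covariate]]
    if (is.null(x)) stop("covariate ", ef$covariate, " not found")
    mult <- if (ef$form == "continuous_power") {
      if (x <= 0) stop("non-positive covariate in continuous_power effect: ",
                       ef$covariate)
      (x / ef$reference)^ef$theta_j
    } else {
      ef$theta_j^x
    }
    p[[ef$parameter]] <- p[[ef$parameter]] * mult
  }
  full_eta <- c(CL = 0, V1 = 0, Q = 0, V2 = 0)
  if (length(eta)) {
    if (is.null(names(eta))) {
      stop("eta must be named")
    }
    full_eta[names(eta)] <- eta
  }
  pk_params(p[["CL"]] * exp(full_eta[["CL"]]), p[["V1"]] * exp(full_eta[["V1"]]),
            p[["Q"]] * exp(full_eta[["Q"]]), p[["V2"]] * exp(full_eta[["V2"]]))
}

#' Model specification
#'
#' @param error_model `"proportional"` or `"combined"` (additive +
#'   proportional) residual error.
#' @param iiv Character vector naming the parameters carrying log-normal
#'   inter-individual variability (diagonal omega; no eta correlations).
#' @param effects List of [covariate_effect()] terms.
#' @return A `model_spec` list.
#' @export
model_spec <- function(error_model = c("proportional", "combined"),
                       iiv = c("CL", "V1", "Q", "V2"), effects = list()) {
  error_model <- match.arg(error_model)
  stopifnot(all(iiv %in% c("CL", "V1", "Q", "V2")))
  structure(list(error_model = error_model, iiv = iiv, effects = effects),
            class = "model_spec")
}

# Internal: covariate-adjusted typical value matrix (n_subjects x 4)
tpmat_of <- function(theta, effects, subjects) {
  t(vapply(subjects, function(s) {
    unclass(individual_parameters(theta, effects, s$covariates))
  }, numeric(4)))
}

subjects_for_cpp <- function(subjects) {
  lapply(subjects, function(s) {
    s[c("y", "times", "starts", "rates", "durations")]
  })
}

iiv_index <- function(iiv) {
  match(iiv, c("CL", "V1", "Q", "V2")) - 1L  # 0-based for C++
}

#' FOCE-I objective function value
#'
#' Computes the first-order conditional estimation (with interaction)
#' approximation to -2 log-likelihood. Per subject, the conditional mode
#' `eta_hat` of the random effects maximizes the joint density of the data
#' and `eta`; the model is linearized about `eta_hat` with gradient
#' `G = df/deta`, the residual variance is evaluated at `eta_hat` (the
#' interaction term), and the contribution is
#' `log|C| + r' C^{-1} r` with `C = G Omega G' + V(eta_hat)` and
#' `r = y - f(eta_hat) + G eta_hat`. The additive `2 pi` constant is
#' omitted, matching the usual NONMEM convention.
#'
#' @param ds Dataset data frame (see [read_dataset()]).
#' @param spec A [model_spec()].
#' @param theta Typical values ([pk_params()]).
#' @param omega Named log-scale IIV SDs for `spec$iiv`.
#' @param sigma_prop Proportional residual SD.
#' @param sigma_add Additive residual SD (ng/mL).
#' @return List with `ofv` and `ebe` (subjects x length(iiv) matrix of
#'   conditional modes).
#' @export
foce_objective <- function(ds, spec, theta, omega, sigma_prop,
                           sigma_add = 0) {
  subjects <- dataset_to_subjects(ds)
  foce_objective_subjects(subjects, spec, theta, omega, sigma_prop, sigma_add)
}

foce_objective_subjects <- function(subjects, spec, theta, omega, sigma_prop,
                                    sigma_add = 0, eta_start = NULL) {
  theta <- as_pk_params(theta)
  m <- length(spec$iiv)
  om <- rep(0, m)
  if (m > 0) {
    if (is.null(names(omega))) names(omega) <- spec$iiv
    om <- unname(omega[spec$iiv])
    if (any(is.na(om)) || any(om < 0)) stop("invalid omega")
  }
  tpmat <- tpmat_of(theta, spec$effects, subjects)
  if (is.null(eta_start)) eta_start <- matrix(0, length(subjects), max(m, 1))
  res <- .foce_ofv_cpp(subjects_for_cpp(subjects), tpmat, iiv_index(spec$iiv),
                       om^2, sigma_prop, sigma_add, eta_start)
  ebe <- res$eta
  if (m > 0) colnames(ebe) <- spec$iiv
  list(ofv = res$ofv, ebe = ebe, ok = res$ok)
}

#' Chi-square threshold for objective-function comparisons
#'
#' Upper-`alpha` quantile of the chi-square distribution, the drop in OFV
#' required of a nested model extension at significance level `alpha`
#' (3.84 for `alpha = 0.05`, `df = 1`).
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Scalar threshold.
#' @export
chi2_threshold <- function(alpha, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  stats::qchisq(1 - alpha, df)
}

# ---- parameter vector packing --------------------------------------------

pack_init <- function(spec, init) {
  par <- log(unclass(as_pk_params(init$theta)))
  names(par) <- paste0("l", c("CL", "V1", "Q", "V2"))
  for (i in seq_along(spec$effects)) {
    ef <- spec$effects[[i]]
    val <- if (!is.null(init$effect_theta) && length(init$effect_theta) >= i) {
      init$effect_theta[i]
    } else if (ef$form == "categorical_exponent") 1 else 0
    par <- c(par, if (ef$form == "categorical_exponent") log(val) else val)
    names(par)[length(par)] <- paste0("ef", i, "_", ef$parameter, ".", ef$covariate)
  }
  for (p in spec$iiv) {
    par <- c(par, log(init$omega[[p]]))
    names(par)[length(par)] <- paste0("lom_", p)
  }
  par <- c(par, lsig_prop = log(init$sigma_prop))
  if (spec$error_model == "combined") {
    par <- c(par, lsig_add = log(init$sigma_add))
  }
  par
}

unpack_par <- function(par, spec) {
  theta <- pk_params(exp(par[[1]]), exp(par[[2]]), exp(par[[3]]), exp(par[[4]]))
  k <- 4
  effects <- spec$effects
  for (i in seq_along(effects)) {
    k <- k + 1
    effects[[i]]$theta_j <- if (effects[[i]]$form == "categorical_exponent") {
      exp(par[[k]])
    } else {
      par[[k]]
    }
  }
  omega <- stats::setNames(numeric(length(spec$iiv)), spec$iiv)
  for (p in spec$iiv) {
    k <- k + 1
    omega[[p]] <- exp(par[[k]])
  }
  k <- k + 1
  sigma_prop <- exp(par[[k]])
  sigma_add <- 0
  if (spec$error_model == "combined") {
    k <- k + 1
    sigma_add <- exp(par[[k]])
  }
  list(theta = theta, effects = effects, omega = omega,
       sigma_prop = sigma_prop, sigma_add = sigma_add)
}

default_init <- function(spec) {
  list(theta = pk_params(40, 20, 15, 30),
       omega = stats::setNames(rep(0.3, 4), c("CL", "V1", "Q", "V2")),
       sigma_prop = 0.2, sigma_add = 1)
}

fd_hessian <- function(fn, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
    for (j in seq_len(n)[-seq_len(i)]) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h
      xmm[c(i, j)] <- x[c(i, j)] - h
      xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
      xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
      H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
    }
  }
  H
}

#' Fit the population model by FOCE-I
#'
#' Maximum-likelihood estimation of the two-compartment population model
#' under the FOCE-I approximation. Fixed effects, IIV SDs and residual SDs
#' are optimized on the log scale (continuous-covariate exponents on the
#' natural scale) by BFGS with the per-subject conditional modes warm-started
#' from the previous outer iteration. Standard errors come from a central
#' finite-difference Hessian of the OFV (covariance `2 H^{-1}`), transformed
#' by the delta method; shrinkage is `(1 - SD(ebe)/omega) * 100`.
#'
#' @param ds Dataset data frame.
#' @param spec A [model_spec()].
#' @param init Optional list with `theta` ([pk_params()]), `omega` (named),
#'   `sigma_prop`, `sigma_add`, `effect_theta`.
#' @param compute_se Compute RSEs via the finite-difference Hessian
#'   (adds one Hessian evaluation; disable inside bootstrap loops).
#' @param max_outer Maximum BFGS iterations.
#' @return A `popk_fit` object: estimates, `ofv`, `ebe`, `rse` (percent),
#'   `shrinkage` (percent), `converged`, plus the spec and data needed by
#'   the diagnostic routines.
#' @export
fit_model <- function(ds, spec = model_spec(), init = NULL,
                      compute_se = TRUE, max_outer = 300) {
  subjects <- dataset_to_subjects(ds)
  if (!length(subjects)) stop("empty dataset")
  if (any(vapply(subjects, function(s) length(s$y) == 0, logical(1)))) {
    stop("every subject needs at least one usable observation")
  }
  ini <- default_init(spec)
  if (!is.null(init)) ini[names(init)] <- init
  par0 <- pack_init(spec, ini)

  m <- length(spec$iiv)
  env <- new.env()
  env$eta_warm <- matrix(0, length(subjects), max(m, 1))
  ofv_fn <- function(par) {
    res <- tryCatch({
      u <- unpack_par(par, spec)
      sp <- spec
      sp$effects <- u$effects
      foce_objective_subjects(subjects, sp, u$theta, u$omega, u$sigma_prop,
                              u$sigma_add, eta_start = env$eta_warm)
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    if (m > 0) env$eta_warm <- res$ebe
    res$ofv
  }
  ofv0 <- ofv_fn(par0)
  opt <- stats::optim(par0, ofv_fn, method = "BFGS",
                      control = list(maxit = max_outer, reltol = 1e-10))
  converged <- opt$convergence == 0 && opt$value < 1e9
  u <- unpack_par(opt$par, spec)
  spec_u <- spec
  spec_u$effects <- u$effects
  final <- foce_objective_subjects(subjects, spec_u, u$theta, u$omega,
                                   u$sigma_prop, u$sigma_add,
                                   eta_start = env$eta_warm)

  est <- c(unclass(u$theta),
           stats::setNames(vapply(u$effects, `[[`, numeric(1), "theta_j"),
                           vapply(u$effects, function(e)
                             paste0(e$parameter, ".", e$covariate), character(1))),
           if (length(spec$iiv)) stats::setNames(u$omega, paste0("omega_", spec$iiv)),
           sigma_prop = u$sigma_prop)
  if (spec$error_model == "combined") est <- c(est, sigma_add = u$sigma_add)

  rse <- stats::setNames(rep(NA_real_, length(est)), names(est))
  if (compute_se && converged) {
    H <- tryCatch(fd_hessian(ofv_fn, opt$par, h = 1e-3), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv)) {
        se_par <- sqrt(pmax(diag(cv), 0))
        # delta method: parameters on log scale have SE(x) = x * SE(log x);
        # continuous-covariate exponents are on the natural scale already
        natural <- rep(FALSE, length(opt$par))
        for (i in seq_along(spec$effects)) {
          if (spec$effects[[i]]$form == "continuous_power") natural[4 + i] <- TRUE
        }
        se_nat <- ifelse(natural, se_par, abs(est) * se_par)
        rse <- 100 * se_nat / pmax(abs(est), 1e-12)
      }
    }
  }

  shrink <- stats::setNames(rep(NA_real_, m), spec$iiv)
  ebe <- final$ebe
  if (m > 0) {
    for (k in seq_len(m)) {
      omk <- u$omega[[spec$iiv[k]]]
      shrink[k] <- if (omk > 0) (1 - stats::sd(ebe[, k]) / omk) * 100 else NA_real_
    }
  }
  structure(list(
    theta = u$theta, effects = u$effects, omega = u$omega,
    sigma_prop = u$sigma_prop, sigma_add = u$sigma_add,
    ofv = final$ofv, ofv_init = ofv0, estimates = est, rse = rse,
    ebe = ebe, shrinkage = shrink, converged = converged,
    spec = spec, subjects = subjects, data = ds, par = opt$par
  ), class = "popk_fit")
}

#' @export
print.popk_fit <- function(x, ...) {
  cat("Two-compartment population PK fit (FOCE-I)\n")
  cat(sprintf("  OFV: %.3f   converged: %s   subjects: %d\n",
              x$ofv, x$converged, length(x$subjects)))
  tab <- data.frame(estimate = x$estimates, rse_pct = x$rse)
  print(round(tab, 4))
  if (length(x$shrinkage)) {
    cat("  eta shrinkage (%):",
        paste(sprintf("%s=%.1f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- stepwise covariate screening ----------------------------------------

#' Default covariate-effect candidates
#'
#' All four disposition parameters crossed with the screened covariates.
#' `SEX`, `ECMO`, `CRRT` enter as categorical fold-changes; the rest as
#' normalized powers with the dataset median as reference.
#'
#' @param ds Dataset data frame (for reference medians).
#' @param parameters Parameters to screen.
#' @param covariates Covariate columns to screen.
#' @return List of [covariate_effect()] candidates.
#' @export
default_candidates <- function(ds, parameters = c("CL", "V1", "Q", "V2"),
                               covariates = c("AGE", "WT", "SEX", "ALT", "SCR",
                                              "CRCL", "EGFR", "ECMO", "CRRT")) {
  categorical <- c("SEX", "ECMO", "CRRT")
  first_rows <- ds[!duplicated(ds$ID), ]
  out <- list()
  for (p in parameters) {
    for (cv in covariates) {
      if (!cv %in% names(ds)) next
      out[[length(out) + 1]] <- if (cv %in% categorical) {
        covariate_effect(p, cv, "categorical_exponent", theta_j = 1)
      } else {
        covariate_effect(p, cv, "continuous_power", theta_j = 0,
                         reference = stats::median(first_rows[[cv]]))
      }
    }
  }
  out
}

effect_label <- function(ef) paste0(ef$parameter, "~", ef$covariate)

fit_quiet <- function(ds, spec, init, ...) {
  tryCatch(fit_model(ds, spec, init = init, compute_se = FALSE, ...),
           error = function(e) NULL)
}

#' Forward stepwise covariate selection
#'
#' Univariate forward inclusion: at each step every remaining candidate is
#' added to the current model on its own, and the candidate with the largest
#' OFV drop is included if the drop is at least `threshold` (3.84 for
#' alpha = 0.05, df = 1). Ties are broken by lexicographic
#' parameter~covariate label. Candidate fit failures are recorded in the
#' trace, not fatal.
#'
#' @param ds Dataset data frame.
#' @param base A [model_spec()] to start from.
#' @param candidates List of [covariate_effect()] candidates
#'   ([default_candidates()] if `NULL`).
#' @param threshold Required OFV decrease.
#' @param init Optional initial values passed to every fit.
#' @return List with `spec` (selected model), `fit` (its fit) and `trace`
#'   (every tested delta-OFV).
#' @export
forward_selection <- function(ds, base = model_spec(), candidates = NULL,
                              threshold = 3.84, init = NULL) {
  if (is.null(candidates)) candidates <- default_candidates(ds)
  trace <- data.frame()
  base_fit <- fit_model(ds, base, init = init, compute_se = FALSE)
  current <- base
  current_fit <- base_fit
  remaining <- candidates
  step <- 0
  repeat {
    step <- step + 1
    if (!length(remaining)) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cand_spec <- current
      cand_spec$effects <- c(current$effects, list(remaining[[i]]))
      f <- fit_quiet(ds, cand_spec, init)
      fits[[i]] <- f
      deltas[i] <- if (is.null(f)) NA_real_ else current_fit$ofv - f$ofv
      trace <- rbind(trace, data.frame(
        step = step, effect = effect_label(remaining[[i]]),
        ofv = if (is.null(f)) NA_real_ else f$ofv, delta_ofv = deltas[i],
        failed = is.null(f), selected = FALSE
      ))
    }
    ok <- which(!is.na(deltas) & deltas >= threshold)
    if (!length(ok)) break
    labs <- vapply(remaining, effect_label, character(1))
    best <- ok[order(-deltas[ok], labs[ok])][1]
    trace$selected[nrow(trace) - length(remaining) + best] <- TRUE
    current$effects <- c(current$effects, remaining[best])
    current_fit <- fits[[best]]
    remaining <- remaining[-best]
  }
  list(spec = current, fit = current_fit, trace = trace)
}

#' Backward covariate elimination
#'
#' Repeatedly removes the effect whose removal increases the OFV the least,
#' while that increase is below `threshold` (10.82 as printed for
#' alpha = 0.001, df = 1); effects whose removal costs at least `threshold`
#' are retained.
#'
#' @param ds Dataset data frame.
#' @param full A [model_spec()] containing the effects to test.
#' @param threshold Required OFV increase for retention.
#' @param init Optional initial values.
#' @return List with `spec`, `fit`, `trace` as in [forward_selection()].
#' @export
backward_elimination <- function(ds, full, threshold = 10.82, init = NULL) {
  trace <- data.frame()
  current <- full
  current_fit <- fit_model(ds, full, init = init, compute_se = FALSE)
  step <- 0
  while (length(current$effects)) {
    step <- step + 1
    increases <- rep(NA_real_, length(current$effects))
    fits <- vector("list", length(current$effects))
    for (i in seq_along(current$effects)) {
      red <- current
      red$effects <- current$effects[-i]
      f <- fit_quiet(ds, red, init)
      fits[[i]] <- f
      increases[i] <- if (is.null(f)) NA_real_ else f$ofv - current_fit$ofv
      trace <- rbind(trace, data.frame(
        step = step, effect = effect_label(current$effects[[i]]),
        ofv = if (is.null(f)) NA_real_ else f$ofv, delta_ofv = increases[i],
        failed = is.null(f), removed = FALSE
      ))
    }
    ok <- which(!is.na(increases) & increases < threshold)
    if (!length(ok)) break
    labs <- vapply(current$effects, effect_label, character(1))
    drop_i <- ok[order(increases[ok], labs[ok])][1]
    trace$removed[nrow(trace) - length(current$effects) + drop_i] <- TRUE
    current$effects <- current$effects[-drop_i]
    current_fit <- fits[[drop_i]]
  }
  list(spec = current, fit = current_fit, trace = trace)
}
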