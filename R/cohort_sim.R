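#' @useDynLib remipopk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Truncated (log-)normal samplers calibrated so that the *truncated*
# distribution hits a target median: the location parameter is solved by
# uniroot, then sampling is by inverse-CDF. Keeps Table-style
# "median (range)" summaries reproducible without hand-tuned locations.
rtrunc_norm <- function(n, median, sd, lower, upper) {
  med_of <- function(m) {
    u <- (stats::pnorm(lower, m, sd) + stats::pnorm(upper, m, sd)) / 2
    stats::qnorm(min(max(u, 1e-12), 1 - 1e-12), m, sd)
  }
  lo <- lower
  hi <- upper
  while (med_of(lo) > median && lo > lower - 50 * sd) lo <- lo - sd
  while (med_of(hi) < median && hi < upper + 50 * sd) hi <- hi + sd
  m <- stats::uniroot(function(m) med_of(m) - median, c(lo, hi), tol = 1e-8)$root
  u <- stats::runif(n, stats::pnorm(lower, m, sd), stats::pnorm(upper, m, sd))
  stats::qnorm(u, m, sd)
}

rtrunc_lnorm <- function(n, median, sdlog, lower, upper) {
  exp(rtrunc_norm(n, log(median), sdlog, log(lower), log(upper)))
}

#' Sample covariate profiles emulating the study population
#'
#' Draws demographic and laboratory covariates matching the cohort of 32
#' critically ill adults: median age 62 y (26-79), weight 63 kg (47-98),
#' 3:1 male:female ratio, skewed liver/renal labs (ALT, SCR sampled
#' truncated log-normal), total protein and albumin truncated normal, ECMO
#' probability 18/32 and CRRT 14/32. Creatinine clearance (Cockcroft-Gault)
#' and eGFR (CKD-EPI 2009) are derived per subject. Covariates are sampled
#' independently; no correlation structure is imposed.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed; `NULL` leaves the RNG state alone.
#' @return A data frame with columns `AGE`, `WT`, `SEX` (0 male, 1 female),
#'   `ALT`, `SCR`, `TP`, `ALB`, `ECMO`, `CRRT`, `CRCL`, `EGFR`.
#' @export
sample_covariates <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  age <- rtrunc_norm(n, median = 62, sd = 13.22, lower = 26, upper = 79)
  wt <- rtrunc_norm(n, median = 63, sd = 12, lower = 47, upper = 98)
  sex <- stats::rbinom(n, 1, 8 / 32)
  alt <- rtrunc_lnorm(n, median = 34.85, sdlog = 0.8, lower = 7.8, upper = 549.2)
  scr <- rtrunc_lnorm(n, median = 75.75, sdlog = 0.6, lower = 42.1, upper = 911.77)
  tp <- rtrunc_norm(n, median = 55.4, sd = 8.57, lower = 26.82, upper = 85.29)
  alb <- rtrunc_norm(n, median = 30.4, sd = 4.87, lower = 15.97, upper = 51.7)
  ecmo <- stats::rbinom(n, 1, 18 / 32)
  crrt <- stats::rbinom(n, 1, 14 / 32)
  renal <- derive_renal(age, wt, sex, scr)
  data.frame(
    AGE = age, WT = wt, SEX = sex, ALT = alt, SCR = scr, TP = tp, ALB = alb,
    ECMO = ecmo, CRRT = crrt, CRCL = renal$CrCL, EGFR = renal$eGFR
  )
}

#' Renal function derived covariates
#'
#' Cockcroft-Gault creatinine clearance and the CKD-EPI 2009 creatinine
#' eGFR. Serum creatinine is supplied in umol/L and converted to mg/dL
#' (divide by 88.4) internally; the Cockcroft-Gault value carries the 0.85
#' female factor. The CKD-EPI race coefficient is not applied (no such
#' covariate is recorded).
#'
#' @param age Age, years.
#' @param weight Body weight, kg.
#' @param sex 0 male, 1 female (vectorized).
#' @param SCR Serum creatinine, umol/L, > 0.
#' @return A list with `CrCL` (mL/min) and `eGFR` (mL/min/1.73 m^2).
#' @export
derive_renal <- function(age, weight, sex, SCR) {
  if (any(SCR <= 0) || any(age <= 0) || any(weight <= 0)) {
    stop("age, weight and SCR must be positive")
  }
  scr_mgdl <- SCR / 88.4
  crcl <- (140 - age) * weight / (72 * scr_mgdl) * ifelse(sex == 1, 0.85, 1)
  kappa <- ifelse(sex == 1, 0.7, 0.9)
  alpha <- ifelse(sex == 1, -0.329, -0.411)
  ratio <- scr_mgdl / kappa
  egfr <- 141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.209 *
    0.993^age * ifelse(sex == 1, 1.018, 1)
  list(CrCL = crcl, eGFR = egfr)
}

#' Sample infusion regimens emulating the study dosing
#'
#' Constant-rate infusions with rates drawn truncated log-normal on
#' [2, 17.28] mg/h (median 6) and durations truncated log-normal on
#' [6.15, 294.9] h (median 8.33), matching the reported dosing summaries.
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return A list of [regimen()] objects, each a single segment from time 0.
#' @export
sample_regimens <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rate <- rtrunc_lnorm(n, median = 6, sdlog = 0.45, lower = 2, upper = 17.28)
  dur <- rtrunc_lnorm(n, median = 8.33, sdlog = 1.0, lower = 6.15, upper = 294.9)
  lapply(seq_len(n), function(i) constant_infusion(rate[i], dur[i]))
}

#' Population model specification for simulation
#'
#' Bundles typical values, log-scale inter-individual variability (IIV)
#' standard deviations, residual-error magnitudes and covariate effects.
#' IIV percentages reported as CV% are interpreted as `100 * sqrt(omega^2)`
#' on the log scale, the usual convention for log-normal IIV.
#'
#' @param theta A [pk_params()] of typical values.
#' @param omega Named vector of log-scale IIV SDs for a subset of
#'   `c("CL","V1","Q","V2")`; zero entries mean no IIV on that parameter.
#' @param sigma_prop Proportional residual SD (fraction, e.g. 0.25).
#' @param sigma_add Additive residual SD, ng/mL.
#' @param effects List of [covariate_effect()] terms.
#' @return A `population_model` list.
#' @export
population_model <- function(theta, omega = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                             sigma_prop = 0.25, sigma_add = 0,
                             effects = list()) {
  theta <- as_pk_params(theta)
  om <- c(CL = 0, V1 = 0, Q = 0, V2 = 0)
  if (length(omega)) {
    if (is.null(names(omega)) || !all(names(omega) %in% names(om))) {
      stop("omega must be named with a subset of CL, V1, Q, V2")
    }
    om[names(omega)] <- omega
  }
  if (any(om < 0) || sigma_prop < 0 || sigma_add < 0) {
    stop("omega and sigma components must be >= 0")
  }
  structure(list(theta = theta, omega = om, sigma_prop = sigma_prop,
                 sigma_add = sigma_add, effects = effects),
            class = "population_model")
}

#' Final-model generating values
#'
#' The final population model: typical values CL 58.2 L/h, V1 25.5 L,
#' Q 20.0 L/h, V2 34.5 L; log-normal IIV of 50.3/16.5/65.7/61.2 CV% on
#' CL/V1/Q/V2; proportional residual error of 25%; no covariate effects.
#'
#' @return A [population_model()].
#' @export
default_population_model <- function() {
  population_model(
    theta = typical_params(),
    omega = c(CL = 0.503, V1 = 0.165, Q = 0.657, V2 = 0.612),
    sigma_prop = 0.25, sigma_add = 0
  )
}

# Nominal sampling offsets after dose cessation, hours
post_cessation_offsets <- function() c(0, 10, 20, 30, 60, 90, 120, 240) / 60

#' Simulate a synthetic study cohort
#'
#' Generates a complete dosing/observation dataset under the study design:
#' each subject receives one constant-rate infusion, plasma is sampled at
#' dose cessation and 10/20/30/60/90/120/240 min after stop, individual
#' parameters are `typical * covariate multipliers * exp(eta)` with
#' `eta ~ N(0, diag(omega^2))`, and observations carry combined
#' proportional/additive residual error (negative draws are redrawn).
#' Samples are independently dropped with probability `dropout` (emulating
#' discarded/failed samples) and values below `lloq` are flagged BLQ.
#'
#' @param pop A [population_model()].
#' @param n Number of subjects.
#' @param seed Integer seed (required for a reproducible cohort).
#' @param lloq Lower limit of quantification, ng/mL (assay linear range
#'   starts at 1.0 ng/mL).
#' @param dropout Per-sample independent dropout probability.
#' @param covariates Optional pre-drawn covariate data frame (one row per
#'   subject); drawn via [sample_covariates()] when `NULL`.
#' @param regimens Optional list of regimens; drawn via [sample_regimens()]
#'   when `NULL`.
#' @return A dataset data frame (see [read_dataset()] for the column
#'   contract) with attributes `individual_params` (n x 4 matrix) and
#'   `eta` (n x 4 matrix) recording the latent subject-level truth.
#' @export
simulate_cohort <- function(pop, n = 32, seed = NULL, lloq = 1.0,
                            dropout = 0.08, covariates = NULL,
                            regimens = NULL) {
  if (!inherits(pop, "population_model")) stop("pop must be a population_model")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates)) covariates <- sample_covariates(n)
  if (is.null(regimens)) regimens <- sample_regimens(n)
  stopifnot(nrow(covariates) == n, length(regimens) == n)

  pnames <- c("CL", "V1", "Q", "V2")
  eta <- sapply(pnames, function(p) {
    if (pop$omega[[p]] > 0) stats::rnorm(n, 0, pop$omega[[p]]) else rep(0, n)
  })
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, pnames))
  ipar <- t(vapply(seq_len(n), function(i) {
    unclass(individual_parameters(pop$theta, pop$effects,
                                  covariates[i, , drop = FALSE], eta[i, ]))
  }, numeric(4)))
  colnames(ipar) <- pnames

  offsets <- post_cessation_offsets()
  rows <- lapply(seq_len(n), function(i) {
    reg <- regimens[[i]]
    t_end <- max(reg$start + reg$duration)
    tobs <- t_end + offsets
    f <- conc_profile(pk_params(ipar[i, 1], ipar[i, 2], ipar[i, 3], ipar[i, 4]),
                      reg, tobs)
    y <- rep(-1, length(f))
    bad <- rep(TRUE, length(f))
    while (any(bad)) {
      k <- sum(bad)
      y[bad] <- f[bad] * (1 + stats::rnorm(k, 0, pop$sigma_prop)) +
        stats::rnorm(k, 0, pop$sigma_add)
      bad <- y < 0
    }
    keep <- stats::runif(length(y)) >= dropout
    dose <- data.frame(ID = i, TIME = reg$start, AMT = reg$rate * reg$duration,
                       RATE = reg$rate, EVID = 1, DV = NA_real_, MDV = 1,
                       BLQ = 0)
    obs <- data.frame(ID = i, TIME = tobs[keep], AMT = 0, RATE = 0, EVID = 0,
                      DV = y[keep], MDV = 0,
                      BLQ = as.integer(y[keep] < lloq))
    out <- rbind(dose, obs)
    cbind(out, covariates[rep(i, nrow(out)), , drop = FALSE], row.names = NULL)
  })
  ds <- do.call(rbind, rows)
  ds <- ds[order(ds$ID, ds$TIME, -ds$EVID), ]
  rownames(ds) <- NULL
  attr(ds, "individual_params") <- ipar
  attr(ds, "eta") <- eta
  ds
}
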