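#' Context-sensitive decrement time
#'
#' Time after stopping a constant-rate infusion of the given duration for
#' the plasma concentration to fall by `decrement` percent of its value at
#' cessation, computed from the population-predicted (typical-value) curve
#' by bracketed bisection. The 50% case is the context-sensitive half-time
#' (CSHT). By linearity the result does not depend on the infusion rate.
#'
#' @param params A [pk_params()] object.
#' @param rate Infusion rate, mg/h.
#' @param duration Infusion duration, h (> 0).
#' @param decrement Percent decrement, in (0, 100).
#' @return Decrement time in minutes.
#' @export
csdt <- function(params, rate = 12, duration, decrement = 50) {
  params <- as_pk_params(params)
  if (decrement <= 0 || decrement >= 100) stop("decrement must be in (0, 100)")
  if (duration <= 0) stop("duration must be > 0")
  reg <- constant_infusion(rate, duration)
  c_end <- conc_profile(params, reg, duration)
  target <- (1 - decrement / 100) * c_end
  g <- function(s) conc_profile(params, reg, duration + s) - target
  upper <- 1
  while (g(upper) > 0 && upper < 1e6) upper <- upper * 2
  if (g(upper) > 0) stop("failed to bracket the decrement time")
  stats::uniroot(g, c(0, upper), tol = 1e-6)$root * 60
}

#' Context-sensitive decrement-time table
#'
#' Evaluates [csdt()] over a grid of infusion durations and decrement
#' percentages, and reports for each decrement curve its maximum relative
#' change beyond 24 h of infusion (the plateau metric: the study's curves
#' all plateau after 24 h).
#'
#' @param params A [pk_params()] object.
#' @param rate Infusion rate, mg/h.
#' @param durations Infusion durations, h.
#' @param decrements Decrement percentages.
#' @return A `csdt_table` list: `table` (long data frame of duration,
#'   decrement, minutes), `plateau` (per-decrement max relative change
#'   beyond 24 h; `NA` when fewer than two grid durations are >= 24 h).
#' @export
csdt_grid <- function(params, rate = 12,
                      durations = c(0.5, 1, 2, 4, 8, 12, 16, 24, 36, 48, 72),
                      decrements = seq(10, 90, by = 10)) {
  if (!length(durations) || !length(decrements)) stop("empty grid")
  tab <- expand.grid(duration = sort(durations), decrement = sort(decrements))
  tab$minutes <- mapply(function(d, q) csdt(params, rate, d, q),
                        tab$duration, tab$decrement)
  plateau <- vapply(sort(decrements), function(q) {
    v <- tab$minutes[tab$decrement == q & tab$duration >= 24]
    if (length(v) < 2) return(NA_real_)
    (max(v) - min(v)) / min(v)
  }, numeric(1))
  names(plateau) <- sort(decrements)
  structure(list(table = tab, plateau = plateau, rate = rate),
            class = "csdt_table")
}

#' Monte Carlo concentration bands under a dosing regimen
#'
#' Simulates `n` subjects with log-normal inter-individual variability (no
#' residual error on the latent curve) under the given regimen and returns
#' 5th/50th/95th percentile concentration bands on a dense time grid.
#' Loading doses should be encoded as 1-minute infusion segments in the
#' regimen.
#'
#' @param pop A [population_model()]; covariate effects are ignored unless
#'   `covariates` rows are supplied.
#' @param reg A [regimen()].
#' @param n Number of simulated subjects.
#' @param seed Integer seed.
#' @param horizon Simulation end time, h.
#' @param n_grid Number of grid points.
#' @param covariates Optional covariate data frame (recycled over subjects)
#'   for populations with covariate effects.
#' @return A `sim_bands` list: `time`, `p5`, `p50`, `p95`, `typical` (the
#'   typical-value curve), `regimen`.
#' @export
simulate_bands <- function(pop, reg, n = 1000, seed = NULL, horizon = NULL,
                           n_grid = 241, covariates = NULL) {
  if (!inherits(pop, "population_model")) stop("pop must be a population_model")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(horizon)) horizon <- max(reg$start + reg$duration) + 4
  tgrid <- seq(0, horizon, length.out = n_grid)
  pnames <- c("CL", "V1", "Q", "V2")
  cmat <- matrix(NA_real_, n, length(tgrid))
  for (i in seq_len(n)) {
    eta <- stats::setNames(stats::rnorm(4, 0, pop$omega[pnames]), pnames)
    cov_i <- if (is.null(covariates)) {
      data.frame(row.names = 1)
    } else {
      covariates[((i - 1) %% nrow(covariates)) + 1, , drop = FALSE]
    }
    p <- individual_parameters(pop$theta, pop$effects, cov_i, eta)
    cmat[i, ] <- conc_profile(p, reg, tgrid)
  }
  q <- apply(cmat, 2, stats::quantile, c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(time = tgrid, p5 = q[1, ], p50 = q[2, ], p95 = q[3, ],
                 typical = conc_profile(pop$theta, reg, tgrid), regimen = reg),
            class = "sim_bands")
}
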