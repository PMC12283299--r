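#' Two-compartment disposition parameters
#'
#' Container for the four structural parameters of the mammillary
#' two-compartment model: elimination clearance `CL` (L/h), central volume
#' `V1` (L), inter-compartmental clearance `Q` (L/h) and peripheral volume
#' `V2` (L).
#'
#' @param CL Elimination clearance, L/h.
#' @param V1 Central compartment volume, L.
#' @param Q Inter-compartmental clearance, L/h.
#' @param V2 Peripheral compartment volume, L.
#' @return An object of class `pk_params` (named numeric vector).
#' @examples
#' pk_params(CL = 58.2, V1 = 25.5, Q = 20.0, V2 = 34.5)
#' @export
pk_params <- function(CL, V1, Q, V2) {
  p <- c(CL = unname(CL), V1 = unname(V1), Q = unname(Q), V2 = unname(V2))
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all four disposition parameters must be finite and strictly positive")
  }
  structure(p, class = "pk_params")
}

#' Default typical parameter values
#'
#' The final-model population typical values for remimazolam in critically
#' ill adults: CL 58.2 L/h, V1 25.5 L, Q 20.0 L/h, V2 34.5 L.
#'
#' @return A `pk_params` object.
#' @export
typical_params <- function() {
  pk_params(CL = 58.2, V1 = 25.5, Q = 20.0, V2 = 34.5)
}

#' Micro and hybrid rate constants
#'
#' Reparameterizes clearances/volumes into micro rate constants
#' (`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`) and the hybrid
#' distribution/terminal rate constants `lambda_fast > lambda_slow`
#' (conventionally alpha and beta), roots of
#' `lambda^2 - (k10+k12+k21) lambda + k10 k21 = 0`, with the corresponding
#' half-lives `ln(2)/lambda`.
#'
#' @param params A [pk_params()] object.
#' @return A named list with `k10`, `k12`, `k21`, `lambda_fast`,
#'   `lambda_slow`, `t_half_fast`, `t_half_slow` (rates 1/h, half-lives h).
#' @export
micro_constants <- function(params) {
  params <- as_pk_params(params)
  k10 <- params[["CL"]] / params[["V1"]]
  k12 <- params[["Q"]] / params[["V1"]]
  k21 <- params[["Q"]] / params[["V2"]]
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  lf <- (s + disc) / 2
  ls <- (s - disc) / 2
  list(
    k10 = k10, k12 = k12, k21 = k21,
    lambda_fast = lf, lambda_slow = ls,
    t_half_fast = log(2) / lf, t_half_slow = log(2) / ls
  )
}

as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  x <- unlist(x)
  if (!all(c("CL", "V1", "Q", "V2") %in% names(x))) {
    stop("expected CL, V1, Q, V2")
  }
  pk_params(x[["CL"]], x[["V1"]], x[["Q"]], x[["V2"]])
}

#' Infusion regimen
#'
#' A regimen is a set of constant-rate infusion segments; overlapping
#' segments superpose (rates add). Loading doses are represented as 1-minute
#' constant-rate segments (`rate = amount * 60` mg/h) rather than
#' instantaneous boluses.
#'
#' @param start Segment start times, h (vectorized).
#' @param rate Infusion rates, mg/h; must be >= 0.
#' @param duration Segment durations, h; must be > 0.
#' @return A `pk_regimen` data frame sorted by `start`.
#' @examples
#' # 6 mg loading dose over 1 min followed by 12 mg/h maintenance for 8 h
#' regimen(start = c(0, 1 / 60), rate = c(6 * 60, 12), duration = c(1 / 60, 8 - 1 / 60))
#' @export
regimen <- function(start, rate, duration) {
  if (length(start) != length(rate) || length(start) != length(duration)) {
    stop("start, rate, duration must have equal length")
  }
  if (length(start) && (any(rate < 0) || any(duration <= 0) || any(!is.finite(start)))) {
    stop("rates must be >= 0 and durations > 0")
  }
  ord <- order(start)
  structure(
    data.frame(start = start[ord], rate = rate[ord], duration = duration[ord]),
    class = c("pk_regimen", "data.frame")
  )
}

#' Single constant-rate infusion from time zero
#'
#' @param rate Infusion rate, mg/h.
#' @param duration Infusion duration, h.
#' @return A `pk_regimen`.
#' @export
constant_infusion <- function(rate, duration) {
  regimen(start = 0, rate = rate, duration = duration)
}

#' Plasma concentration under a piecewise-constant infusion regimen
#'
#' Exact closed-form central-compartment concentration of the two-compartment
#' model by superposition of constant-rate infusion segments (switching an
#' infusion off is superposing a negative-rate infusion). The mg/L model
#' solution is scaled to ng/mL here and only here.
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()].
#' @param times Evaluation times, h, all >= 0.
#' @return Numeric vector of concentrations, ng/mL.
#' @export
conc_profile <- function(params, reg, times) {
  params <- as_pk_params(params)
  if (any(times < 0)) stop("times must be >= 0")
  if (!inherits(reg, "pk_regimen")) stop("reg must be a pk_regimen")
  if (nrow(reg) == 0) return(rep(0, length(times)))
  as.numeric(.conc2_cpp(params[["CL"]], params[["V1"]], params[["Q"]],
                        params[["V2"]], reg$start, reg$rate, reg$duration,
                        times))
}

#' Time to reach a fraction of the steady-state concentration
#'
#' Under a constant-rate infusion the plateau is `rate/CL`; this returns the
#' smallest time at which the concentration reaches `fraction` of that
#' plateau, by bracketed root-finding on the closed-form accumulation curve.
#' By linearity of the kinetics the answer does not depend on the rate.
#'
#' @param params A [pk_params()] object.
#' @param rate Infusion rate, mg/h (any positive value; result is
#'   rate-independent).
#' @param fraction Target fraction of steady state, in (0, 1).
#' @return Time in hours.
#' @export
time_to_css_fraction <- function(params, rate = 12, fraction = 0.9) {
  params <- as_pk_params(params)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  css <- rate / params[["CL"]] * 1000
  # long-but-finite horizon: accumulation is governed by lambda_slow
  hc <- micro_constants(params)
  upper <- 2
  f <- function(t) {
    conc_profile(params, constant_infusion(rate, upper + 1), t) / css - fraction
  }
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-9)$root
}
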