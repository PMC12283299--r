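# Independent oracles used across the suite.

# Numerical integration of the two-compartment amount ODEs under a
# piecewise-constant infusion regimen; returns central concentration (ng/mL)
# and compartment amounts. Independent of the package's closed form.
ode_oracle <- function(params, reg, times, rtol = 1e-10, atol = 1e-10) {
  k <- micro_constants(params)
  rate_in <- function(t) {
    sum(reg$rate[t >= reg$start & t < reg$start + reg$duration])
  }
  deriv <- function(t, state, parms) {
    a1 <- state[1]; a2 <- state[2]
    list(c(
      rate_in(t) - (k$k10 + k$k12) * a1 + k$k21 * a2,
      k$k12 * a1 - k$k21 * a2,
      params[["CL"]] * a1 / params[["V1"]]   # cumulative eliminated amount
    ))
  }
  tt <- sort(unique(c(0, reg$start, reg$start + reg$duration, times)))
  out <- deSolve::lsoda(c(0, 0, 0), tt, deriv, NULL, rtol = rtol, atol = atol)
  idx <- match(times, out[, 1])
  list(
    conc = as.numeric(out[idx, 2]) / params[["V1"]] * 1000,
    A1 = as.numeric(out[idx, 2]), A2 = as.numeric(out[idx, 3]),
    eliminated = as.numeric(out[idx, 4])
  )
}

# Adaptive-quadrature marginal -2 log-likelihood for a one-subject,
# one-random-effect model (IIV on CL, additive residual error), with the
# same additive-constant convention as the FOCE objective (2*pi omitted).
quad_m2ll_oracle <- function(y, times, reg, theta, omega, sigma_add) {
  lik <- function(eta) {
    vapply(eta, function(e) {
      p <- pk_params(theta[["CL"]] * exp(e), theta[["V1"]], theta[["Q"]],
                     theta[["V2"]])
      f <- conc_profile(p, reg, times)
      exp(sum(stats::dnorm(y, f, sigma_add, log = TRUE)) +
            stats::dnorm(e, 0, omega, log = TRUE))
    }, numeric(1))
  }
  val <- stats::integrate(lik, -12 * omega, 12 * omega,
                          rel.tol = 1e-13, abs.tol = 0,
                          subdivisions = 500L)$value
  -2 * log(val) - length(y) * log(2 * pi)
}

# Minimal single-infusion dataset builder for fitting tests.
toy_dataset <- function(y, times, rate = 12, duration = 8, id = 1,
                        covariates = NULL) {
  ds <- rbind(
    data.frame(ID = id, TIME = 0, AMT = rate * duration, RATE = rate,
               EVID = 1, DV = NA_real_, MDV = 1, BLQ = 0),
    data.frame(ID = id, TIME = times, AMT = 0, RATE = 0, EVID = 0, DV = y,
               MDV = 0, BLQ = 0)
  )
  if (!is.null(covariates)) ds <- cbind(ds, covariates[rep(1, nrow(ds)), , drop = FALSE])
  ds
}

table2_init <- function() {
  list(theta = typical_params(),
       omega = c(CL = 0.4, V1 = 0.2, Q = 0.5, V2 = 0.5),
       sigma_prop = 0.2, sigma_add = 1)
}
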