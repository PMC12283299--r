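---
title: "Methods: population pharmacokinetics of remimazolam under continuous infusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of remimazolam under continuous infusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remipopk)
```

## The problem

Remimazolam is an ultra-short-acting benzodiazepine increasingly used for
sedation in intensive care. Its kinetics in critically ill adults — often on
ECMO or CRRT, with impaired hepatic and renal function — cannot be assumed
to match healthy-volunteer data. The analysis implemented here models sparse
elimination-phase concentration data collected after stopping continuous
infusions in a 32-subject ICU cohort, asks whether any routine covariate
shifts the disposition parameters, validates the model internally, and uses
it to answer the clinically decisive question: how fast do concentrations
fall after an infusion is stopped, and does that depend on how long the
infusion ran (the context-sensitive decrement time, CSDT)?

Because the underlying patient-level data are not public, the package ships
a synthetic-cohort generator that reproduces the study design and the
published summaries. Every downstream stage — estimation, screening,
validation, simulation — is exercised and tested against that generator.

## Structural model

Disposition is a mammillary two-compartment model parameterized by
clearance $CL$ (L/h), central volume $V_1$ (L), inter-compartmental
clearance $Q$ (L/h) and peripheral volume $V_2$ (L), with micro constants
$k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and hybrid rate
constants $\lambda_{1,2}$ solving
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$.

Input is restricted to piecewise-constant infusions (the clinical route:
micropump infusion; loading doses are represented as 1-minute constant-rate
segments rather than boluses, which avoids a second code path and matches
"x mg given within 1 min" dosing). The central concentration under a
constant-rate segment has a closed form, and arbitrary regimens follow by
superposition — switching an infusion off is superposing a negative-rate
infusion. Amounts are in mg, volumes in L, times in h; the single
mg/L → ng/mL factor of 1000 lives in `conc_profile()` alone.

Two numerical details:

* near-degenerate hybrid roots ($\lambda_1 \approx \lambda_2$, relative gap
  below $10^{-8}$) switch to the analytic repeated-root limit of the
  two-exponential form, keeping the profile continuous in the parameters;
* the closed form is verified in the test suite against adaptive numerical
  integration of the compartment ODE system (via deSolve) to $10^{-6}$
  relative error, and mass balance (dose = amounts remaining + amount
  eliminated) to $10^{-4}$.

The typical values used for simulation are the final-model estimates:
$CL = 58.2$ L/h, $V_1 = 25.5$ L, $Q = 20.0$ L/h, $V_2 = 34.5$ L, giving a
terminal half-life of about 1.7 h.

## Random effects and residual error

Inter-individual variability is log-normal and diagonal:
$\theta_i = \theta_{tv} \cdot e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$,
independently per parameter (no $\eta$ correlations are estimated; none are
reported for this model). Published IIV percentages are interpreted as
$100\sqrt{\omega^2}$ on the log scale, the dominant convention for
log-normal IIV, so e.g. 50.3% IIV on CL means $\omega_{CL} = 0.503$.

Residual error is proportional by default,
$y_{ij} = f_{ij}(1 + \varepsilon_{p,ij})$ with
$\varepsilon_p \sim N(0, \sigma_p^2)$ and $\sigma_p = 0.25$ as the
generating value; a combined additive + proportional model is available
(`model_spec("combined")`) since the study screened both before settling on
proportional-only.

## Covariate model

Continuous covariates enter as normalized powers,
$\theta_i = \theta_{tv} (\mathrm{COV}/\mathrm{COV}_{med})^{\theta_j}$,
and categorical (0/1) covariates as fold-changes,
$\theta_i = \theta_{tv}\, \theta_j^{\mathrm{COV}}$, both multiplicative
with the random effect. Candidates cross the four disposition parameters
with age, weight, sex, ALT, serum creatinine, derived creatinine clearance
(Cockcroft–Gault, with µmol/L → mg/dL conversion and the 0.85 female
factor), eGFR (CKD-EPI 2009 creatinine equation, no race coefficient — the
cohort records none) and the ECMO/CRRT flags.

Screening is stepwise by objective function value (OFV, $-2$ log-likelihood
up to a constant): forward univariate inclusion requires a drop of at least
3.84 ($\chi^2_1$ at $\alpha = 0.05$); backward elimination retains an
effect only if its removal raises the OFV by at least 10.82 (the printed
$\alpha = 0.001$ threshold; the exact $\chi^2_1$ quantile is 10.828 and
`chi2_threshold(0.001, 1)` returns it — the stepwise default keeps the
conventional printed 10.82). Ties in a step are broken deterministically by
the smaller model, then lexicographic effect label.

## Estimation: FOCE with interaction

The marginal likelihood of a nonlinear mixed-effects model has no closed
form. The engine implements first-order conditional estimation with
interaction (FOCE-I): per subject,

1. the conditional mode $\hat\eta_i$ maximizes the joint density of the
   subject's data and $\eta$ (a damped Newton search with finite-difference
   derivatives, warm-started from the previous outer iteration);
2. the model is linearized at $\hat\eta_i$ with gradient
   $G_i = \partial f_i/\partial\eta|_{\hat\eta_i}$;
3. the residual variance $V_i$ is evaluated at $\hat\eta_i$ (the
   "interaction");
4. the subject contributes
   $\log|C_i| + r_i^\top C_i^{-1} r_i$ with
   $C_i = G_i \Omega G_i^\top + V_i$ and
   $r_i = y_i - f_i(\hat\eta_i) + G_i\hat\eta_i$,

the $2\pi$ constants being omitted as is conventional. The outer problem
optimizes $\log\theta$, $\log\omega$, $\log\sigma$ (continuous-covariate
exponents on their natural scale) by BFGS. Standard errors come from a
central finite-difference Hessian of the OFV (covariance $2H^{-1}$) with
the delta method back to the natural scale; shrinkage is
$(1 - \mathrm{SD}(\hat\eta)/\omega) \times 100$. BLQ observations
(below 1.0 ng/mL, the assay's lower limit) are excluded from fitting — the
sparse elimination-phase design out to 240 min makes them rare, and no
more elaborate rule is reported for the original analysis.

The per-subject inner loop and the closed-form concentration model are
implemented in C++ (RcppArmadillo); replicate studies (parameter recovery,
bootstrap, screening operating characteristics) each involve thousands of
inner optimizations.

Correctness anchors in the test suite:

* with no random effects the objective reduces to the weighted
  least-squares closed form;
* on a one-random-effect toy subject with additive error and
  $\omega = 3\times10^{-4}$ — small enough that $e^\eta$ is linear over the
  entire $\eta$ mass, i.e. an effectively linear-Gaussian model where
  FOCE-I is exact — the objective matches the adaptive-quadrature marginal
  $-2$ log-likelihood to $10^{-6}$ (the discrepancy scales linearly to zero
  with $\omega$, the signature of the neglected skewness term);
* the OFV is additive over subjects, invariant to ID permutation, and
  shifts by exactly $n\log s^2$ under a consistent rescaling of
  concentrations, dose rates and additive error.

## Synthetic cohort

The generator reproduces the study conditions as defaults, not as dials:

* 32 subjects; one constant-rate infusion each, rate truncated log-normal
  on [2, 17.28] mg/h with median 6, duration truncated log-normal on
  [6.15, 294.9] h with median 8.33;
* sampling at dose cessation and 10/20/30/60/90/120/240 min after stop
  (eight nominal samples);
* covariates drawn from truncated normal (age 62 [26–79], weight 63
  [47–98], total protein, albumin) or truncated log-normal (ALT 34.85
  [7.8–549.2], SCR 75.75 [42.1–911.77]) marginals targeting the published
  medians and ranges; sex 3:1 M:F, ECMO 18/32, CRRT 14/32; renal indices
  derived per subject. Location parameters are calibrated by root-finding
  so the *truncated* distribution hits the target median exactly. Where the
  published dispersion column is ambiguous (it mixes SDs and IQRs without
  per-row labels) the generator targets medians and ranges only, and
  spread values are chosen once at plausible magnitudes (e.g. weight SD
  12 kg);
* covariates are sampled independently — no correlation structure is
  published; this is a stated simplification;
* per-sample dropout probability 0.08 emulates the discarded/failed
  samples (243 collected, 236 analyzed, of a nominal 256), giving an
  expected ~236 retained observations; values below 1 ng/mL are flagged
  BLQ; concentrations above the 1000 ng/mL upper assay bound are kept and
  only warned about, since no discard rule is reported;
* daily laboratory values are collapsed to a single baseline per subject.

What the generator deliberately does not emulate: outlier contamination
(the study's seven "unreasonably higher or lower" samples are represented
only through dropout), ECMO-circuit adsorption or CRRT clearance physics
(the study found no covariate effect of either, so the flags are pure
labels), assay error structure beyond the combined residual model, and
time-varying covariates. Passing recovery and calibration tests on this
generator therefore demonstrates internal consistency of the estimation
and validation machinery under the study design — not robustness to
features of real ICU data the generator omits.

## Internal validation

* **CWRES** under the FOCE linearization,
  $C_i^{-1/2}(y_i - f_i(\hat\eta_i) + G_i\hat\eta_i)$, approximately
  standard normal for a correct model (~95% within ±2).
* **Bootstrap**: subjects (not rows) resampled with replacement, each
  replicate refit from the original estimates (the standard
  stability/speed choice); medians and 2.5/97.5 percentiles over converged
  replicates; more than 50% non-convergence is a hard failure. The method's
  convention is 1000 replicates; the analysis script uses 200 and the
  tests fewer, which widens nothing but the Monte Carlo error of the CI
  endpoints.
* **pcVPC**: 1000 simulated replicates on the observed design; observed
  and simulated values are prediction-corrected by
  median(PRED in bin)/PRED; bins sit at the eight nominal post-cessation
  times (the design is nominally timed, so quantile binning would only
  blur it); empty bins cannot arise under this binning because every
  observation maps to its nearest nominal offset. Reported alongside the
  percentile bands is the fraction of observations inside the simulated
  90% prediction interval.
* **NPDE**: per subject, 1000 simulated replicate vectors; observed and
  simulated vectors decorrelated by the empirical simulation mean and
  Cholesky factor; pde = fraction of decorrelated simulations below the
  decorrelated observation (ties half-counted), clipped to
  $[1/2K, 1 - 1/2K]$; npde = $\Phi^{-1}$(pde). Three tests are always run —
  Wilcoxon signed rank for location, a $\chi^2_n$ scale test of
  $\sum \mathrm{npde}^2$ for the variance (the natural reading of the
  study's unreferenced "Fisher's variance test"), Shapiro–Wilk for shape —
  with a Bonferroni global test, rather than adjudicating "when
  appropriate" case by case. A singular simulation covariance receives a
  $10^{-8}$ ridge.

One calibration subtlety: the variance of npde *within one dataset* is
approximately 1 under the correct model, but its dispersion *across*
replicate datasets exceeds the iid $\sqrt{2/n}$ because linear
decorrelation cannot remove all nonlinear within-subject dependence. The
package's end-to-end calibration check therefore averages the NPDE mean
and variance over six replicate cohorts of the study's size before
comparing them to the published-magnitude bands.

## Simulations and decrement times

Dose simulations draw 1000 subjects with IIV (no residual error on the
latent curve) and report 5/50/95% bands. CSDTs are computed from the
population-predicted (typical-value) curve — following the study's wording
— not from Monte Carlo medians: the time $s$ after stopping an infusion of
duration $D$ at which $C(D+s) = (1 - q/100)\,C(D)$, found by bracketed
root-finding to $10^{-6}$ h; the reference concentration is the value at
the moment of cessation. By linearity the result is rate-independent. The
decrement surface spans 10–90% × 0.5–72 h at 12 mg/h, and a plateau metric
(maximum relative change of each decrement curve beyond 24 h) quantifies
the "curves plateau after 24 h" observation.

A worked consistency note: with the typical values above, the closed-form
half-time after a 0.5-h infusion evaluates to ≈14.7 min against the
published 15.6 min, while the 2-h and 8-h values (≈17.5, ≈21.1 min) agree
closely with the published 18 and 21 min. The source of the 0.5-h gap
(time-grid resolution or a slightly different parameter set in the original
simulation) is not recoverable from the publication; the package reports
the closed-form value as computed.

## Design choices on open points

* **Loading doses** "3–8 mg/min" vs "3–8 mg within 1 min": read as total
  amounts infused over 1 minute (rate = amount × 60 mg/h), the reading
  consistent with the results narrative.
* **Sex-effect operating characteristics**: when simulating the
  documented 1.3-fold female CL effect at the study's 24 M / 8 F, the
  generating residual IIV on CL is set to 24.7% (the bootstrap-median IIV)
  rather than the 50.3% final-model estimate: with 50.3% the published
  forward-step dOFV of 6.24 for a 1.3-fold effect would be a far upper-tail
  event (expected noncentrality ≈ 1.6), whereas 24.7% makes the published
  numbers mutually consistent (implied effect $\sqrt{6.24}\cdot
  \omega\sqrt{1/8+1/24} \approx \log 1.29$). Under that regime the forward
  3.84 rule retains and the backward 10.82 rule removes the effect in the
  majority of replicates, reproducing the study's screening narrative.
* **Type-I error of screening** is checked with a reduced random-effects
  model (IIV on CL only): the likelihood-ratio calibration of a
  fixed-effect covariate test does not depend on the size of the correctly
  specified nuisance model, and the reduction makes 200-replicate studies
  cheap.
* **V1's IIV** is retained in all scans despite its high shrinkage (the
  published 69% suggests the sparse design barely informs it); whether the
  original scans kept it is unstated.
* **Structural alternatives**: one- and three-compartment variants were
  screened in the original study; this package fixes the two-compartment
  structure (the published final model) and does not refit the comparison.

## Problem sizes

Chosen as the package's defaults for its replicate studies: parameter
recovery uses 20 replicates of 32 subjects; screening calibration 200
single-test replicates; the sex-effect study 30 replicates; bootstrap 200
replicates in the analysis script; pcVPC/NPDE 1000 simulations as in the
study. All are reproducible from fixed seeds.

## Known limitations

No effect-site compartment or pharmacodynamic (sedation-score) linkage; no
metabolite kinetics; no inter-occasion variability or $\eta$ correlations;
BLQ handling by exclusion rather than likelihood-based (M3) treatment;
covariates sampled independently; CSDTs are plasma, not effect-site,
decrement times — the study itself notes a two-compartment plasma model
cannot separate the two.
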