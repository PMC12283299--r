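# remipopk

Population pharmacokinetics of remimazolam under continuous intravenous
infusion in critically ill adults, as a tested, reproducible R pipeline.

Remimazolam is an ultra-short-acting benzodiazepine used for ICU sedation.
For clinicians the decisive kinetic question is how quickly plasma
concentrations fall once an infusion is stopped — and whether that depends
on how long the infusion ran. This package implements the full analysis
chain used to answer it in a sparse-sampling ICU study: a two-compartment
disposition model, nonlinear mixed-effects estimation, covariate screening,
internal validation, and Monte Carlo dose simulation with
context-sensitive decrement times (CSDT). It is aimed at pharmacometricians
and methods-minded intensivists who want every number in the analysis to be
recomputable from code.

## The model

Disposition is a mammillary two-compartment model with parameters CL (L/h),
V1 (L), Q (L/h), V2 (L), micro constants k10 = CL/V1, k12 = Q/V1,
k21 = Q/V2, and hybrid rate constants solving
λ² − (k10+k12+k21)λ + k10·k21 = 0. Input is piecewise-constant infusion;
profiles are exact closed forms by superposition. Between-subject
variability is log-normal (θ_i = θ_tv·e^η), residual error proportional;
estimation is first-order conditional with interaction (FOCE-I), covariate
screening is stepwise by objective-function value (forward ΔOFV ≥ 3.84,
backward ΔOFV ≥ 10.82), and validation uses CWRES, a subject-resampling
bootstrap, prediction-corrected VPC and normalized prediction distribution
errors (NPDE). Because no patient-level data are public, a synthetic-cohort
generator reproduces the study design (32 subjects, infusions of
2–17.28 mg/h for 6.15–294.9 h, samples at dose cessation and
10/20/30/60/90/120/240 min after stop, published covariate marginals) so
every stage is testable end to end.

## Worked example

```r
library(remipopk)

p <- typical_params()   # CL 58.2 L/h, V1 25.5 L, Q 20.0 L/h, V2 34.5 L
micro_constants(p)$t_half_slow
#> [1] 1.696179

# context-sensitive half-times at 12 mg/h
sapply(c(0.5, 2, 8), function(d) csdt(p, 12, d, 50))
#> [1] 14.69743 17.47677 21.09281

time_to_css_fraction(p, 12, 0.9)
#> [1] 2.979087
```

The half-times (minutes) barely grow with infusion duration — the kinetic
signature that makes the drug suitable for long ICU infusions — and a
constant-rate infusion reaches 90% of its plateau (rate/CL, 206.2 ng/mL at
12 mg/h) in about 3 h.

Fitting a synthetic cohort generated under the final-model values:

```r
ds <- simulate_cohort(default_population_model(), n = 32, seed = 42)
fit <- fit_model(ds, model_spec("proportional"))
fit
#> Two-compartment population PK fit (FOCE-I)
#>   OFV: 1369.439   converged: TRUE   subjects: 32
#>            estimate rse_pct
#> CL          54.4956  9.4478
#> V1          21.2376 13.6273
#> Q           22.7689 14.5805
#> V2          32.9101 12.5567
#> omega_CL     0.4773 12.9576
#> omega_V1     0.0002  0.0000
#> omega_Q      0.3399 68.4476
#> omega_V2     0.5371 28.4170
#> sigma_prop   0.2646  7.6844
#>   eta shrinkage (%): CL=0.2, V1=100.0, Q=55.7, V2=14.9
```

One 32-subject cohort recovers the generating values (CL 58.2, V1 25.5,
Q 20.0, V2 34.5, σ_prop 0.25) within sampling error; the collapsed
omega_V1 with ~100% shrinkage reflects how little the sparse
elimination-phase design says about V1's variability.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — generate and summarize the cohort
2. `02_fit_base_model.R` — FOCE-I fit, estimates/RSE/shrinkage table
3. `03_covariate_scan.R` — forward (3.84) / backward (10.82) screening
4. `04_model_evaluation.R` — CWRES, bootstrap, pcVPC, NPDE
5. `05_dose_simulations.R` — concentration bands, CSDT surface

Run them in order with `Rscript analysis/0X_*.R` from the repository root.

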