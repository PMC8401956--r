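# rtteclz

Repeated time-to-event (RTTE) modelling of positive-symptom improvement in
schizophrenia spectrum disorder patients after starting clozapine.

Clozapine response is slow and highly variable: some patients improve
within weeks, others only after years, and improvement can be lost and
regained. `rtteclz` models the *hazard* of a positive-symptom improvement
event as a parametric function of time since the first clozapine dose,
shared across repeated improvements within a patient, and asks which
patient characteristics shift that hazard.

## The model

Conditional on a patient-level frailty, event histories follow a
nonhomogeneous Poisson process with intensity

    h(t) = theta1 * exp(eta) * g(t; theta2) * exp( sum_k theta_k (x_k - c_k) )

where

* `g(t)` is the baseline time course: `1` (constant hazard),
  `exp(theta2 * t)` (Gompertz) or `t^theta2` (Weibull, zero hazard at
  `t = 0` for positive shape);
* `x_k` are covariates (age, concomitant atypical antipsychotic, cumulative
  six-month clozapine dose, ...), continuous ones centered at the cohort
  median `c_k`, so `exp(theta_k)` is an adjusted hazard ratio per unit;
* `eta ~ N(0, omega2)` is a log-normal frailty capturing inter-individual
  variability in the baseline hazard (reported as `IIV% = 100 * sqrt(omega2)`).

Estimation maximizes the Laplace-approximated marginal likelihood; nested
models are compared by likelihood ratio on the objective function value
(OFV, -2 log-likelihood). Covariates are selected by univariate screening,
forward addition (p < 0.05) and backward elimination (p < 0.01). The final
model is checked with simulation-based Kaplan-Meier visual predictive
checks (KM-VPC) and sampling-importance-resampling (SIR) uncertainty.

Because the source clinic records are not public, the package ships a
synthetic cohort generator that reproduces the published cohort's
demographic marginals, dosing and censoring structure and draws event
histories from a specified hazard model, so the entire workflow is testable
end to end.

## Worked example

```r
library(rtteclz)

# a 116-subject synthetic cohort generated from the published final model
coh <- generate_cohort(cohort_spec(n_subjects = 116), seed = 1)

# final-model fit (Weibull frailty hazard, published centering constants)
fit <- fit_rtte(
  fit_spec("weibull", covariates = c("AGE", "AAP", "CTDD"),
           centers = c(AGE = 41, CTDD = 34)),
  coh$data)
print(fit)
```

```
<rtte_fit> weibull hazard, 116 subjects, 21709 events
OFV: 10637.97   converged: TRUE
 Parameter   Estimate RSE%   aHR            95% CI
    theta1   0.002430 12.8     - 0.001819-0.003041
    theta2   0.846800  1.5     -     0.8223-0.8712
       AGE  -0.057130 16.6 0.944       0.927-0.962
       AAP   1.294000 19.6  3.65         2.22-5.99
      CTDD   0.008721 45.6  1.01            1-1.02
   IIV_pct 100.600000  7.6     -       85.68-115.5
```

The scale and shape say the improvement hazard is near zero on the day
clozapine is started and rises steeply over the first half-year. Each year
of age above 41 lowers the hazard about 5% on this replicate (aHR 0.94); a
concomitant atypical antipsychotic multiplies it by ~3.7; each gram of
cumulative six-month dose above 34 g adds ~1%. `IIV_pct` near 100% means a
one-SD frailty shift scales a patient's hazard e-fold. Estimates scatter
around the generating values (0.0022, 0.853, -0.0438, 1.39, 0.0183,
IIV 101%) with the sampling noise of a 116-subject cohort.

Model checking:

```r
bm <- run_base_models(coh$data)           # constant vs Gompertz vs Weibull
v  <- km_vpc(fit$model, coh$data, n_sim = 1000, seed = 2)
plot(v)                                   # observed KM inside 95% band
s  <- sir(fit, coh$data, seed = 3)        # SIR RSEs and percentile CIs
```

`run_full_pipeline(run_config(...))` chains every stage (cohort or CSV
input, base-model comparison, screen, stepwise, final fit, SIR, VPCs) and
writes all tables plus a reproducibility manifest to an output directory.

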