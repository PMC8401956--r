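---
title: "Methods: repeated time-to-event modelling of clozapine response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated time-to-event modelling of clozapine response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtteclz)
```

## The modelling problem

Positive symptoms (hallucinations, delusions, disorganized thinking) in
treatment-resistant schizophrenia can improve, deteriorate and improve
again during long-term clozapine treatment. `rtteclz` treats each
documented improvement as a recurrent event on the calendar-time axis that
starts at the first clozapine dose, with the end of follow-up as a
right-censoring time, and models the event intensity parametrically so
that covariate effects, uncertainty and predictions can all be derived
from one likelihood.

## Model structure and assumptions

Conditional on a subject-level frailty `eta`, the event history is a
nonhomogeneous Poisson process with intensity

$$h(t \mid \eta, x) \;=\; \theta_1 e^{\eta}\, g(t;\theta_2)\,
  \exp\!\Big(\sum_k \theta_k (x_k - c_k)\Big),$$

with baseline time courses $g(t) = 1$ (constant), $e^{\theta_2 t}$
(Gompertz) or $t^{\theta_2}$ (Weibull). The conditional log-likelihood of
one subject with event times $t_j$ and censoring time $T$ is
$\sum_j \log h(t_j) - \int_0^T h(u)\,du$; the integral has a closed form
in every family, split at covariate change points when a covariate path is
piecewise constant. The frailty is $\eta \sim N(0, \omega^2)$ and is
integrated out per subject by a Laplace approximation.

Key structural assumptions, all deliberate:

* **Calendar-time clock.** The hazard is a function of time since the
  first dose and does *not* reset at an event: the baseline families are
  defined on the treatment-time axis and repeated improvements share the
  same $h(t)$. A gap-time (renewal) formulation was considered and
  rejected because the time courses are expressed in weeks since
  treatment onset.
* **Continuously at risk.** Deterioration episodes are not observed, so no
  improved/deteriorated state is modelled; every subject is at risk of an
  improvement event from first dose until censoring.
* **Frailty on the scale only.** $e^\eta$ multiplies $\theta_1$; because
  the effect is multiplicative on the whole intensity, applying it to the
  scale or to the hazard as a whole is mathematically identical.
* **Static six-month cumulative dose.** The cumulative dose reached after
  six months (CTDD, grams) enters as one per-subject value applied over
  the whole time axis, including the first 26 weeks; the data provide no
  basis for a time-varying treatment of it.

## Estimation

The marginal likelihood is maximized over
$(\log\theta_1, \theta_2, \theta_k, \log\omega^2)$ with `nlminb`
(box constraints keep the Weibull shape above $-1$); "false convergence"
returns are retried from the terminal point and accepted only if the
objective is stationary. The inner frailty mode is found by a damped
Newton search: with $\ell(\eta) = S_0 + n\eta - e^\eta H_0 -
\eta^2/2\omega^2$ the objective is strictly concave, so the search is
globally convergent; tolerance is 1e-10 on the gradient. Every objective
evaluation uses per-subject sufficient statistics (event count, sums of
$\log t_j$ and $t_j$, covariate sums at events, covariate-constant
segments), so its cost is independent of the number of events.

Standard errors come from the inverse numerical Hessian on the transformed
scale, mapped to the natural scale by the delta method. Reporting follows
pharmacometric convention: RSE% $= 100\,SE/|\hat\theta|$; 95% intervals
$\hat\theta \pm 1.96\,SE$ (equivalently $\hat\theta(1 \pm 1.96\,
\mathrm{RSE}/100)$), exponentiated for hazard ratios; inter-individual
variability as $100\sqrt{\omega^2}$ (the alternative
$100\sqrt{e^{\omega^2}-1}$ CV formula is not used). Absolute OFVs retain
all normalizing constants, so they differ from other software's by a
data-independent constant; all OFV *differences* are comparable.

### Accuracy of the Laplace approximation

The Laplace step is exact for $\omega^2 = 0$ and its error grows with the
frailty variance: against 64-node adaptive Gauss–Hermite quadrature (which
itself matches brute-force adaptive quadrature to ~1e-10) the per-subject
marginal log-likelihood deviates by roughly 1e-3 for $\omega^2 \approx
0.5$ and up to ~1e-2 for $\omega^2 \approx 2$ with few events. This is the
method's intrinsic second-order error, not an implementation artifact; the
test suite asserts agreement at that level. Model comparisons within the
package always use the same approximation on both sides, so LRT decisions
are unaffected at realistic effect sizes.

## Model building

Nested models are compared by the likelihood-ratio statistic
$\Delta\mathrm{OFV}$ against exact $\chi^2$ quantiles (3.841 at
$\alpha=0.05$, 6.635 at $\alpha=0.01$, one degree of freedom); printed
thresholds are rounded for display but never used in comparisons, so
borderline decisions cannot flip through rounding. Univariate screening
fits each candidate alone on the base hazard and re-estimates $\omega^2$
in every fit. Forward addition is greedy — each round refits every
remaining candidate and admits the largest significant OFV drop — which
reproduces the natural ordering of effect strength; backward elimination
then removes, iteratively, any retained covariate whose removal costs less
than the $\alpha=0.01$ threshold.

## Simulation and the KM-VPC

Events are simulated by exact inversion of the cumulative hazard on each
covariate-constant segment: the segment count is Poisson with mean equal
to the segment's cumulative hazard and event positions are inverse-CDF
transforms of uniforms (the order-statistics property of the Poisson
process). A thinning sampler is kept in the test suite as an independent
cross-check. `simulate_subject()` guards against runaway histories at
10^4 events by default; the cohort generator and VPC raise that guard
internally because the published parameter scale genuinely produces larger
counts for far-tail frailty draws (below).

The visual predictive check simulates replicate datasets that preserve
each subject's censoring time and covariates (continuous covariates
linearly interpolated on a weekly grid to the 800-week horizon,
categorical carried forward), computes each replicate's Kaplan–Meier curve
and overlays the observed curve on the pointwise 2.5/50/97.5 percentile
band. The KM reduction for repeated events is time-to-*first* improvement
per subject — the standard RTTE-VPC display — with time-to-$k$-th-event
curves available via `kaplan_meier(..., event_number = k)`. Stratified
panels (e.g. cumulative six-month dose $\ge$ 50 g) use the same simulated
replicates per stratum; empty strata are skipped with a warning.

## SIR uncertainty

`sir()` draws 5000 proposal vectors (configurable) from a multivariate
normal centered at the estimates on the transformed scale with covariance
inflated 1.5-fold, weights by likelihood over proposal density, and
resamples 1000 vectors. The published workflow states only "1000 samples";
we read that as the resample count, with the proposal size and single-pass
design as package defaults. RSE% is $100\,SD(\text{resamples})/|\hat\theta|$
(the point estimate, not the resample mean, in the denominator) and
intervals are 2.5/97.5 percentiles. If the effective sample size falls
below 1% of the proposal count the proposal is re-inflated and redrawn (at
most three times).

## The synthetic cohort generator

The original clinic records are not deposited, so `generate_cohort()`
creates stand-in cohorts whose *covariate and censoring structure* matches
the published cohort summary: age ~ N(41.4, 12.2²) years truncated to
[9.2, 78.4]; BMI ~ N(25.6, 5.9²) on [13.3, 46.1]; daily dose ~
N(254.2, 172.4²) mg on [6.25, 825]; female 56.0%, smoker 8.6%; race
multinomial (Malay 21.5%, Chinese 63.8%, Indian 14.7%); concomitant-drug
flags at their reported prevalences; once-daily dosing 44.9%. Covariates
are drawn independently — only marginals are published — except that the
cumulative six-month dose is derived mechanistically as
`daily dose × 182/1000 g` times a log-normal adherence factor
(sdlog 0.25, a modest between-patient adherence spread; meanlog −0.3697
calibrated once so the cohort median is ≈ 34 g, the published centering
constant, and frozen). Censoring times follow a scaled Beta on [8, 800]
weeks with shape (1.009, 1.672), matching the published mean of 306 weeks
with an SD of ≈ 200 weeks (only mean and range are reported; the Beta
shape is a synthetic choice). Non-event follow-up records are placed every
12 weeks, approximating the reported ~27 visits per subject; they only set
the covariate-path resolution and do not enter the likelihood.

Event histories are then drawn from a specified hazard model — by default
the published final model (Weibull scale 0.0022/week, shape 0.853, age
−0.0438/year centered at 41, atypical-antipsychotic 1.39, cumulative-dose
0.0183/g centered at 34, IIV 101%) — and the generating parameters and
per-subject frailties are stored for recovery studies.

**What the generator does not emulate.** The published scale parameter,
taken at face value on the weekly calendar-time axis, implies a typical
cumulative hazard of ≈ 48 by week 306. Cohorts generated from it therefore
contain on the order of a hundred improvement events per subject and
essentially every subject improves — far from the study's observed 122
events among 116 patients (53.4% with ≥ 1 improvement). Those observed
frequencies cannot be reconciled with the printed parameters under any
standard recurrent-event reading, and with the raw data unavailable the
discrepancy cannot be resolved; we keep the printed parameters as the
generating truth. Consequently, passing recovery and VPC tests demonstrate
the *internal* consistency of estimation, selection and simulation under
the published model — not that the generator reproduces the clinical
event sparsity. This is also why far-tail frailty subjects can exceed the
10^4-event guard and the generator raises it rather than aborting.

## Problem sizes used in the automated checks

Parameter recovery refits 1000-subject cohorts over 20 seeds (stepwise
selection over 5 seeds with three active and two null candidates);
simulator calibration uses 10^4 subjects for the mean-count law and 10^5
for the Kolmogorov–Smirnov comparison against the exponential first-event
law; VPC self-consistency uses 116-subject cohorts with 200 replicates
over 4 seeds. These sizes give Monte-Carlo error well below each
assertion's tolerance.

## Known limitations

* Laplace (not adaptive quadrature) estimation: small frailty-variance
  biases at very low event counts are possible, as in any single-mode
  approximation.
* No inter-occasion variability, correlated random effects, or residual
  error model; no dropout/censoring model (VPCs condition on observed
  censoring times).
* Emax parameterizations of dose were not implemented; the exponential
  covariate model is the only covariate form.
* The synthetic cohort draws covariates independently; joint structure
  (e.g. age–dose correlation) is not represented beyond the mechanistic
  dose→cumulative-dose link.
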