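# riskmag

Risk-magnification analysis of heterogeneous treatment benefit for
time-to-event outcomes in randomized trials.

## The problem

A randomized trial reports one overall treatment effect, but the *absolute*
benefit — the risk difference, the quantity that matters for prioritizing
treatment — usually varies widely across enrollees. Under an approximately
constant relative effect, patients at higher baseline risk gain more absolute
benefit: *risk magnification*. This package implements the risk-modeling
workflow for survival outcomes: estimate each subject's baseline outcome risk
from many candidate covariates, estimate how the between-arm risk difference
varies with that risk, and validate both against nonparametric observed
risks. The motivating application is intensive vs standard systolic
blood-pressure treatment and cognitive impairment (probable dementia or
amnestic MCI) in older hypertensive adults, and the bundled synthetic-cohort
generator emulates a trial of that shape (7918 subjects randomized 1:1,
58 candidate baseline covariates, composite cognitive outcomes with roughly
20% event fractions, administrative censoring around a 4.13-year median
follow-up).

## The model

For subject covariates *x*, randomized arm *z* ∈ {0, 1} and a horizon
*t**, the modified elastic-net Cox model is

> λ(t | x, z) = λ₀(t) · exp{ η(x) + z · g(η(x)) }

where

- **η(x) = βᵀx̃** is a baseline risk score on standardized covariates,
  estimated under an elastic-net penalty
  λ·(α‖β‖₁ + (1−α)/2·‖β‖₂²) by cyclic coordinate descent
  (Efron ties, KKT tolerance 10⁻⁷, optional k-fold cross-validated λ);
- **g(η) = γ₀ + γ₁η + γ₂s(η)** is the treatment-interaction function
  (restricted cubic spline *s* with knots at the 0.1/0.5/0.9 quantiles of η),
  fitted unpenalized together with a calibration slope on η;
- absolute risks come from the Breslow baseline cumulative hazard:
  R(x, z) = 1 − exp{−H₀(t*)·e^{η + z·g(η)}}, and the estimated benefit is
  RD(x) = R(x, 1) − R(x, 0), which approaches 0 as η → −∞ (the zero-risk
  constraint, automatic under this hazard form).

The two model blocks are alternated (penalized β-step with the interaction
offset fixed; unpenalized γ-step given η) until the relative change in η
falls below 10⁻⁶.

Validation machinery: Kaplan–Meier observed risks with Greenwood variance,
between-arm risk differences with normal-approximation CIs, Harrell's C,
decile calibration with mean absolute error (MAE), the
Greenwood–Nam–D'Agostino (GND) chi-square test, tertile-of-estimated-benefit
tables, risk-magnification curves with a constant-hazard-ratio reference
RD(r) = (1 − (1 − r)^h) − r and bootstrap bands, a spline-based linearity
test, and a hybrid risk-plus-effect model adding prespecified
subgroup-by-treatment interactions.

## Worked example

```r
library(riskmag)

cohort <- simulate_cohort(cohort_config(n_subjects = 4000, seed = 1))
filt   <- apply_eligibility_filter(cohort)
fit    <- fit_modified_model(filt$cohort, "full", "primary",
                             penalty_spec(lambda = 0.01), seed = 2)
fit
#> Modified elastic-net Cox fit
#>   outcome: primary   covariate set: full
#>   n = 4000  events = 807
#>   nonzero risk-score coefficients: 33 of 58  (lambda = 0.01 , alpha = 0.5 )
#>   interaction g(eta): const = -0.1480, eta = 0.0979, spline1 = -0.0641
#>   alternation: 5 rounds, converged

tertile_benefit_table(fit, filt$cohort, t_star = 4.13)
#> Observed and estimated risk differences by tertile of estimated benefit
#>   High   (-0.0523 to -0.0254): n 680/654, events 270 (39.7%) / 308 (47.1%)
#>          estimated (median) -0.039, observed -0.078 (-0.131 to -0.025), est - obs 0.039
#>   Medium (-0.0253 to -0.0120): n 679/654, events 89 (13.1%) / 79 (12.1%)
#>          estimated (median) -0.017, observed 0.005 (-0.029 to 0.040), est - obs -0.023
#>   Low    (-0.0120 to -0.0000): n 690/643, events 31 (4.5%) / 30 (4.7%)
#>          estimated (median) -0.007, observed -0.002 (-0.024 to 0.021), est - obs -0.006
```

The generative truth here is a constant treatment hazard ratio of 0.85, so
estimated benefit concentrates where baseline risk is high: the high-benefit
tertile carries ~40% event rates and a median estimated risk difference of
−0.039 (39 events prevented per 1000 treated over 4.13 years,
`events_prevented_per_1000(-0.039)`), while the low tertile's estimated
differences shrink toward zero. Discrimination and calibration for this fit:
C = 0.82, decile MAE = 0.015, GND P = 0.27 (consistent with calibration),
linearity P = 0.73 (no evidence the benefit deviates from a linear trend in
the risk score).

`run_pipeline(pipeline_config(...))` runs the full grid — every outcome
definition by every covariate set (full / augmented / basic) — and
`render_report()` writes calibration and magnification plots plus tertile
tables per combination.

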