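# tacropk

Population pharmacokinetics of **continuous-infusion IV tacrolimus** in
pediatric and young-adult hematopoietic cell transplant (HCT) patients —
simulation, nonlinear mixed-effects estimation, diagnostics, and
model-based (Bayesian-forecasting) dose individualization.

Tacrolimus, the calcineurin inhibitor used for graft-versus-host-disease
prophylaxis, has a narrow therapeutic window (institutional trough goal
7–10 ng/ml) and wide inter- and intra-individual kinetic variability,
especially across the pediatric weight range. Fixed weight-based starting
rates (1.25 µg/kg/h) frequently overshoot in the first days of therapy.
This package implements the published two-compartment population model for
this setting and everything needed to study and apply it:

For subject *i*, occasion *j* (one occasion per 24-h infusion bag):

    CL_ij = θ_CL · (WT_i/70)^0.75 · θ_INH^INH(t) · exp(η_CL,i + κ_j)
    V1_i  = θ_V1 · (WT_i/70)^1    · exp(η_V1,i)
    Q_ij  = CL_ij · Fact          V2_i = V1_i · Fact

with log-normal inter-individual (η) and inter-occasion (κ) effects,
proportional residual error, and the published estimates as defaults:
θ_CL = 4.2 L/h, θ_V1 = 61.9 L, θ_INH = 0.8 (CYP3A4/5-inhibitor
co-treatment, i.e. azole antifungals), Fact = 2 fixed, IIV(CL) 26.1%,
IOV(CL) 28.7%, σ 17.9%. The steady-state trough of a continuous infusion
is `rate / CL`, which anchors both the starting-dose rule and the
forecasting logic.

Modules:

* **Kinetics** — closed-form two-compartment propagation
  (`propagate_state()`, `simulate_profile()`), exact for piecewise-constant
  infusion rates.
* **Synthetic cohorts** — `cohort_design()` / `simulate_cohort()` emulate
  the study design (111 subjects, weights 5.5–155.5 kg with median
  23.9 kg, daily troughs drawn 15 min before the next bag for 14 days,
  titration to the 7–10 ng/ml window, ~11.7% of samples under inhibitor).
* **Estimation** — `fit_population()` maximizes an approximate marginal
  likelihood (FOCE-I, full Laplace, or an adaptive-quadrature/Kalman
  filter method; see the methods vignette), `map_estimate()` gives
  empirical-Bayes individual effects, `covariate_step()` runs the stepwise
  covariate search (forward ΔOFV −3.58, backward χ²₁ at α = 0.01).
* **Diagnostics** — `gof_table()` (PRED/IPRED/CWRES) and `vpc()`
  (confidence-interval visual predictive check), with ggplot2 helpers.
* **Dosing** — `initial_rate()` (model-based starting rate) and
  `adaptive_rate()` (MAP Bayesian forecast to a target trough).

A thin command-line wrapper ships at `inst/cli/tacropk-cli.R`
(`simulate`, `fit`, `map`, `dose`, `vpc`, `gof` subcommands).

## Worked example

```r
library(tacropk)

truth <- pop_parameters()          # published estimates
print(truth)
#> Population PK parameters (2-cmt continuous-infusion tacrolimus)
#>   theta_CL  4.2      L/h   (IIV 26.1%, IOV 28.7%)
#>   theta_V1  61.9     L     (IIV 30%)
#>   theta_INH 0.8      (CL multiplier under CYP3A4/5 inhibitor)
#>   Fact      2        (Q = CL*Fact, V2 = V1*Fact)
#>   allometry CL ~ (WT/70)^0.75, V1 ~ (WT/70)^1
#>   sigma_prop 17.9% (proportional residual error)

# a 23.9-kg child started at 1.25 ug/kg/h reaches, noise-free,
sub <- subject_profile("child", 23.9,
                       data.frame(start = 0, duration = 336, rate = 29.9))
round(simulate_profile(sub, truth, c(23.75, 335.75)), 2)
#> [1]  8.79 15.93
# i.e. already near the 10 ng/ml ceiling on day 1 and far above it at
# steady state — the motivation for model-based starts:

initial_rate(truth, weight = 23.9, target_trough = 8.5)
#> Dose recommendation (typical): 15.95 ug/h = 0.6672 ug/kg/h (rounded 0.67)
#> predicted trough 8.5 ng/ml (target 7-10 ng/ml)

# simulate a monitored trial and refit the model
ds <- simulate_cohort(cohort_design(n_subjects = 30, seed = 8), truth)
fit <- fit_population(ds, method = "agq",
                      free = c("theta_cl", "theta_v1", "omega_cl",
                               "pi_cl", "sigma_prop"))
print(fit)
#> Population PK fit (AGQ), OFV = 1918.871
#> 30 subjects, 420 observations; 331 outer evaluations
#>
#> Parameter   Value     RSE      Unit  IIV      IOV
#> theta_CL    3.613     -        L/h   20.5%    21.2%
#> theta_V1    67.12     -        L     30.0%    -
#> theta_INH   0.8       fixed
#> Fact        2         fixed
#> sigma_prop  21.0%     -        (proportional residual error)

# the estimates are a fit's view of THIS 30-subject realization, not of
# the generating constants — this cohort happened to draw low-clearance
# subjects, and the fit tracks them:
lat <- attr(ds, "latent")$effects
round(4.2 * exp(mean(lat$eta_cl)), 2)   # realized typical CL of the draw
#> [1] 3.7
```

At the full study design (111 subjects, `scripts/acceptance.R` below) the
recovered fixed effects sit within a few percent of the generating
values.

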