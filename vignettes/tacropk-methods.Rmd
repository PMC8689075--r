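---
title: "Methods: the tacrolimus continuous-infusion population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tacrolimus continuous-infusion population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`tacropk` implements a hierarchical pharmacokinetic model for tacrolimus
given by 24-h continuous IV infusion to pediatric and young-adult
hematopoietic cell transplant (HCT) patients. The structural model is a
linear two-compartment system with zero-order input. For subject $i$ on
occasion $j$ (one occasion per 24-h infusion bag):

$$
\mathrm{CL}_{i,j} = \theta_{CL}\,(W_i/70)^{0.75}\,
  \theta_{INH}^{\,\mathrm{INH}_i(t)}\, e^{\eta_{CL,i}+\kappa_{j}} ,\qquad
V_{1,i} = \theta_{V1}\,(W_i/70)^{1}\, e^{\eta_{V1,i}},
$$
$$
Q_{i,j} = \mathrm{CL}_{i,j}\cdot \mathrm{Fact}, \qquad
V_{2,i} = V_{1,i}\cdot \mathrm{Fact},
$$

with $\eta_{CL}\sim N(0,\omega_{CL}^2)$, $\eta_{V1}\sim N(0,\omega_{V1}^2)$,
$\kappa_j \sim N(0,\pi_{CL}^2)$ (diagonal covariance; no correlations are
modelled) and proportional residual error
$y = f\,(1+\varepsilon)$, $\varepsilon\sim N(0,\sigma^2)$. Defaults are the
published estimates: $\theta_{CL}=4.2$ L/h, $\theta_{V1}=61.9$ L,
$\theta_{INH}=0.8$, $\mathrm{Fact}=2$ (fixed), $\omega_{CL}=26.1\%$,
$\pi_{CL}=28.7\%$, $\sigma=17.9\%$, allometric exponents fixed at their
theoretic values (0.75 on clearance, 1 on volume) around a 70-kg reference.

Variabilities are reported as percent CV via $100\,\omega$, i.e. the SD of
the log-scale effect; at these magnitudes the distinction from
$100\sqrt{e^{\omega^2}-1}$ is below a percentage point.

Units: concentrations ng/ml ($\equiv$ µg/L), rates µg/h, amounts µg,
volumes L, clearances L/h, times h. These make the steady-state trough of a
continuous infusion exactly `rate / CL`.

**$\omega_{V1}$ is an assumption.** The source analysis includes
$e^{\eta_{V1}}$ in the final model but prints no magnitude for it. The
generator default is $\omega_{V1}=0.30$ (30% CV), a typical volume IIV for
this population; it is configurable and documented as an assumption
wherever it matters.

## Kinetics

The two-compartment system is solved in closed form: over any interval of
constant rate and constant parameters the state is propagated exactly via
the eigendecomposition of the $2\times 2$ rate matrix (two real, distinct,
negative eigenvalues whenever all parameters are positive). Numerical ODE
integration (deSolve) appears only as an independent oracle in the test
suite, where the closed form is required to agree to a relative tolerance
of $10^{-6}$ over randomized parameters and regimens. Overlapping infusion
segments superpose; splitting a bag into sub-segments of equal rate changes
nothing — both properties are asserted as tests.

## The synthetic trial generator

No subject-level data are deposited for the source study, so
`cohort_design()` / `simulate_cohort()` emulate its design and stand in for
the clinical dataset:

* 111 subjects; total body weight from a log-normal with median 23.9 kg,
  truncated to [5.5, 155.5] kg. The log-scale SD (0.64) was chosen once so
  that a cohort of ~111 spans roughly the printed range (the expected
  extreme order statistics at $n=111$ sit near $\pm2.6$ log-SDs); weights
  are drawn by inverse-CDF sampling so each subject consumes a fixed number
  of draws.
* Starting rate 1.25 µg/kg/h; one 24-h bag per day for 14 days; a
  steady-state trough drawn 15 min before the next bag
  ($t = 24k - 0.25$ h).
* Daily titration toward the 7–10 ng/ml window. The clinical protocol's
  adjustment formula is not published; the stand-in rule is: if the trough
  falls outside the window, the next bag's rate is
  `old_rate × 8.5 / trough`, limited to ±50% per day, floored at
  0.1 µg/kg/h. This reproduces the qualitative decay-then-plateau of mean
  infusion rates over the first treatment week.
* CYP3A4/5-inhibitor (azole) co-treatment as a subject-level contiguous
  block of 7 days (azole courses are multi-day), with subject probability
  `0.117 × 14/7` so that 11.7% of observation records are under inhibitor
  in expectation, matching the reported sample fraction.
* Optional geometric censoring after day 10 mimics incomplete 14-day
  records; it is off by default (the default design yields 1,554
  observations, close to the reported 1,648).

The generator emulates the *design*, not the patients: real covariate
distributions (age, diagnosis, conditioning), assay error structure,
irregular sampling times and clinical dose-rounding are not reproduced.
Passing recovery tests on these data therefore demonstrates correctness of
the estimation machinery under the stated model, not transportability to
real records.

A deliberate property of the generator is that the fixed 1.25 µg/kg/h
start frequently produces supratherapeutic day-1 troughs. Note that the
*model-predicted* typical day-1 trough at the median weight is ≈ 8.8 ng/ml,
below the observed 10.2 ng/ml median reported for the study — consistent
with the source's own visual predictive check, which shows the model
under-predicting the day-1 median. The generator inherits the model's
behaviour, not the raw data's.

## Estimation

`fit_population()` minimizes $-2\log$ of an approximate marginal
likelihood. Per subject the random-effect vector
$b = (\eta_{CL}, \eta_{V1}, \kappa_1,\dots,\kappa_J)$ (dimension up to
2 + 14) is profiled by a damped Gauss–Newton search for the joint posterior
mode (`map_estimate()`; gradient tolerance $10^{-6}$, exact residual
derivatives through a finite-difference Jacobian of the prediction).
Occasions without observations carry no $\kappa$: their mode is 0 and they
contribute only prior mass.

Three subject-level marginalizations are provided:

* `method = "foce"` (default): the first-order-conditional-with-interaction
  objective at the mode — marginal covariance
  $V = J\,\Omega\,J^\top + \mathrm{diag}(\sigma^2 f(\hat b)^2)$,
  residual $y - f(\hat b) + J\hat b$.
* `method = "laplace"`: the full Laplace approximation,
  $g(\hat b) - d\log 2\pi + \log\det(\nabla^2 g(\hat b)/2)$, with the
  Hessian from central differences of the analytic gradient.
* `method = "agq"`: adaptive Gauss–Hermite quadrature over
  $(\eta_{CL},\eta_{V1})$ (tensor grid centered at the MAP mode, scaled by
  the mode curvature), combined with a deterministic filter over the
  occasion effects: conditional on $\eta$ the kinetics are linear, so the
  drug amounts are carried as a Gaussian state; each occasion's $\kappa$
  is integrated on Gauss–Hermite nodes, troughs update the state by a
  linear-MMSE (Kalman) step with the proportional-error variance evaluated
  at the predicted mean, and the node mixture is collapsed by moment
  matching at occasion boundaries. With IOV off this reduces to exact
  adaptive quadrature of a linear-Gaussian model.

The outer optimization (`nlminb`) runs on log-transformed positive
parameters (variabilities on the SD scale), with the per-subject modes
warm-started between iterations: at each evaluation the inner search starts
from the better of the previous mode and zero. Standard errors, on request,
come from the numerical Hessian of OFV/2 with a delta-method back-transform.

On small instances (two random effects, a few observations) both
approximations track an adaptive Gauss–Hermite quadrature oracle to within
a fraction of an OFV unit; the test suite asserts this.

**Why three methods, and which to use.** With trough-only sampling and one
observation per occasion, the likelihood surface has a shallow ridge
trading occasion-level and volume-level variability against residual
error, and a subject's random-effect vector has up to 16 dimensions with
very little data per $\kappa$. The error of mode-based expansions (FOCE,
Laplace) is not constant along that ridge: on cohorts simulated at the
default design it pulls their optimum toward smaller random-effect
variability and a larger $\sigma$ — a documented behaviour of
linearization-based estimators on sparse designs, not an implementation
defect (an importance-sampling evaluation of the exact marginal
likelihood, used as a one-off development diagnostic and not shipped as an
estimator, confirmed the exact objective prefers the generating values).
The quadrature-filter method does not show this distortion and is the
method the package's own recovery analyses use; the test suite validates
it against the Gauss–Hermite oracle on small instances. FOCE remains the
default for routine fitting (it is the field's convention and the
fastest), with the caveat above documented.

Even with an accurate integrand, recovered variance components on a single
simulated cohort carry statistical spread: the realized SD of 111
subject-level draws alone fluctuates by about ±7% (1 SD,
$1/\sqrt{2\cdot111}$), and the likelihood's own information on
$\omega_{CL}$ and $\pi_{CL}$ under trough-only sampling adds comparable
uncertainty (the published table prints RSEs for the fixed effects only).
Recovered IIV/IOV values should be read with a spread on the order of
±10% in mind. $\omega_{V1}$ remains the weakest-identified component; the
recovery analyses hold it at its generating value and say so.

The stepwise covariate search (`covariate_step()`) honours the published
forward-inclusion threshold of 3.58 OFV units verbatim (the source labels
it $p<0.05$ although $\chi^2_1(0.05)=3.84$; both are configurable) and a
backward-elimination threshold of $\chi^2_1(0.01)=6.63$, the conventional
reading of "alpha = 0.01" which the source does not make explicit.

## Diagnostics

`gof_table()` reports PRED (effects at zero), IPRED (at the EB modes) and
CWRES under the FOCE linearization — the construction behind the standard
diagnostic panels; on model-simulated data CWRES are approximately standard
normal, asserted in the tests (|mean| < 0.05, SD within [0.9, 1.1] at
>1,000 records). CWRES are reported unitless; a percent scaling appears on
the source's axis labels but is not defined there and is not reproduced.

`vpc()` bins observations by study day (24-h bins by default), tracks the
5th/50th/95th percentiles, and draws `n_sim` (default 500) replicates under
the fitted model with each subject's recorded regimen and sampling times —
the recorded rates are kept fixed, so the simulated bands do not re-titrate
(the standard VPC simplification for adaptive-dosing data). Band level
defaults to 90%.

## Dose individualization

`initial_rate()` uses the steady-state identity trough = rate/CL with the
typical clearance for weight and inhibitor status; the default target is
8.5 ng/ml, the midpoint of the 7–10 ng/ml window. `adaptive_rate()` runs
MAP estimation, propagates the amounts through the recorded dosing history,
and solves for the constant future rate whose predicted concentration at
the horizon (default 24 h, the next trough) equals the target. Because the
kinetics are linear, the predicted concentration is affine in the rate and
the solve is exact (a bisection would converge to the same root); negative
solutions are floored at zero. Future occasions use $\kappa = 0$ (the prior
mode); the running bag keeps its estimated $\kappa$ until it ends.
Per-kg rates are reported raw and rounded to 0.01 µg/kg/h (pump
granularity).

## Numerical choices and degenerate inputs

* Predictions below $10^{-9}$ ng/ml are floored inside the likelihood so
  that $\log(\sigma^2 f^2)$ stays finite for pre-dose observations.
* Simulated concentrations are floored at 0 after residual noise (negative
  observations are impossible; at therapeutic troughs the event is rare).
* Random-effect SDs set to 0 remove the effect from the model entirely
  (the estimation problem shrinks accordingly); with all effects and
  $\sigma$-interaction off, the OFV reduces to the extended least-squares
  objective of the typical-value model.
* Inner Levenberg–Marquardt damping handles indefinite Gauss–Newton
  curvature; a non-positive-definite Laplace Hessian is ridge-regularized.
* One RNG stream per run; the generator consumes a fixed, documented
  number of draws per subject so datasets are bit-reproducible under a
  fixed seed.

## Problem sizes used by the shipped analyses

The package's own acceptance analysis simulates the full study design
(111 subjects × 14 daily troughs) once and refits it (twice: once with the
published structure, once freeing the clearance allometric exponent). The
test suite exercises scaled-down replicates (8–150 subjects, 2–14 days)
chosen so the whole suite runs at desk scale; the covariate type-I-error
calibration uses 200 replicates of a 12-subject, 4-day design with a
single free covariate coefficient, which preserves the calibration
property being tested while keeping each replicate a one-parameter fit.

## Known limitations

* Michaelis–Menten (nonlinear) elimination, time-dependent clearance, oral
  absorption and genotype covariates are out of scope by design.
* The titration rule is a stand-in; only its qualitative behaviour is
  calibrated.
* $\omega_{V1}$ and $\sigma$ are weakly separated by trough-only designs
  (see Estimation); richer sampling would be needed to pin both.
* SEs come from the OFV Hessian only; no bootstrap.
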