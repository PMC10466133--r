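---
title: "In-silico clinical trials for closed-loop anesthetic infusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico clinical trials for closed-loop anesthetic infusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isctsim)
```

# What the package simulates

`isctsim` runs *in-silico clinical trials* (ISCT) of drug-infusion devices:
trials in which the patients are simulated, the sensor is simulated, and the
infusion controller is real code under test. The package is instantiated for
intravenous anesthetic (propofol) delivery, where the clinically relevant
comparison is between

* an **open-loop target-controlled infusion (TCI)** pump, which computes a
  delivery schedule once from a *population* pharmacokinetic (PK) model and
  administers it identically to everyone, and
* a **closed-loop, personalized controller**, which re-estimates each
  subject's individual PK parameters from sparse, noisy, delayed plasma
  concentration measurements (Bayesian MAP estimation) and replans its
  delivery rate as it learns (model-predictive control).

The scientific question a trial answers is distributional: across a cohort of
virtual patients, how tightly does each strategy hold the drug concentration
at the clinical setpoint? The headline statistic is the area of the cohort's
95% prediction interval (PI95) around the target over the equilibrated part
of the trial.

# The physiological model

Drug disposition follows the standard three-compartment mammillary model with
a virtual *effect-site* compartment (the brain, for an anesthetic). With
amounts $A_1, A_2, A_3$ (mg), infusion rate $U(t)$ (mg/min) and plasma
concentration $C_1 = A_1/V_1$:

$$\dot A_1 = A_2 k_{21} + A_3 k_{31} - A_1 (k_{10}+k_{12}+k_{13}) + U(t)$$
$$\dot A_2 = A_1 k_{12} - A_2 k_{21}, \qquad
  \dot A_3 = A_1 k_{13} - A_3 k_{31}$$
$$\dot C_4 = (C_1 - C_4)\, k_{e0}$$

The micro-constants derive from the volume/clearance parameterization:
$k_{10} = CL/V_1$, $k_{12} = Q_2/V_1$, $k_{21} = Q_2/V_2$, $k_{13} = Q_3/V_1$,
$k_{31} = Q_3/V_3$, and the effect-site pair $k_{41} = k_{e0}$,
$k_{14} = k_{e0}/10^4$. Two modeling commitments deserve emphasis:

* **The effect compartment is massless.** $C_4$ is driven by the plasma
  concentration but removes no drug from the central compartment; the
  reverse constant $k_{14}$ is four orders of magnitude below $k_{41}$ and is
  derived and reported for completeness, but carries no mass flux in the
  state equations. Mass balance therefore closes over $A_1+A_2+A_3$ plus
  cumulative elimination, and the package tests it at $10^{-6}$ relative
  tolerance on every simulation.
* **The system is linear and time-invariant** between infusion-rate changes.
  This is what makes an exact solution available and what guarantees that
  doubling the input doubles every response — both used as test invariants.

## Numerical treatment

Three independent solution paths coexist, on purpose:

1. `simulate_pk()` — adaptive stiff-capable integration (`deSolve::lsoda`,
   relative tolerance $10^{-8}$, absolute $10^{-10}$), **restarted at every
   infusion breakpoint** because a rate discontinuity breaks the smoothness
   assumption inside a solver step. A cumulative-elimination state is
   integrated alongside so the mass-balance audit works at solver accuracy
   rather than quadrature accuracy.
2. `analytic_constant_infusion()` — the closed form for a constant rate via
   eigendecomposition of the system matrix, falling back to a
   scaling-and-squaring Taylor exponential if the eigenvector basis is
   ill-conditioned (the matrix is defective only on a measure-zero parameter
   set, but the fallback makes the oracle total). It shares no code with the
   integrator and serves as its oracle: the suite checks agreement below
   $10^{-6}$ relative error over 100 random parameter/rate draws.
3. The C++ propagator — exact stepping of the piecewise-constant system
   through the matrix exponential of the augmented affine system
   $[[M, e_1],[0,0]]$, with the step operator cached per step length.
   Control loops revisit a handful of step lengths thousands of times, so
   this is both exact and roughly two orders of magnitude faster than
   re-integrating; it powers the controller's inner predictions and the
   cohort-scale trial engine. Its agreement with `simulate_pk()` is itself
   under test.

The augmented-matrix form is used instead of solving $Mx = -b$ for the
steady state so that near-singular $M$ (elimination clearance approaching
zero) needs no special-casing.

# Population variability and the virtual cohort

Between-subject variability is log-normal per parameter:
$PAR_k^j = PAR_k\, e^{\eta_k^j}$ with $\eta_k^j \sim N(0, \omega_k^2)$ drawn
independently across parameters and subjects. A parameter with
$\omega_k = 0$ is fixed at its population value. Independence across
parameters is the modeling default here; a correlation structure would be a
config-level extension and is deliberately not invented.

The residual-error (within-subject, measurement-level) model is the combined
additive/proportional form
$$Y = C + \sqrt{prop^2 C^2 + add^2}\;\varepsilon, \qquad
  \varepsilon \sim N(0,1).$$
The square root matters: it makes the two special cases behave as named
(pure additive error has SD `add`, pure proportional error has SD
`prop`·C), and it is the form under which the package's
distribution-recovery tests standardize residuals to a unit normal.

The shipped scenario (`inst/extdata/propofol_reference.yaml`) emulates a
cohort of 1,000 demographically identical subjects — 36-year-old women,
70 kg, 170 cm — with representative published propofol population values for
the reference adult (CL 1.79 L/min, V1 6.28 L, V2 25.5 L, V3 273 L,
Q2 1.75 L/min, Q3 1.11 L/min, ke0 0.146 /min) and log-scale SDs in the
0.46–0.78 range on the six disposition parameters. Demographics are carried
as metadata only: covariate equations mapping demographics to parameters
belong to the published population models themselves and are out of scope
here — parameters always arrive via configuration. At these published-scale
variances, individual plasma concentrations under a common open-loop
schedule deviate from the population prediction by well over 100% in a
1,000-subject cohort, which is exactly the dispersion that motivates
personalization; the acceptance suite checks this.

Reproducibility contract: a cohort is a pure function of
`(population, n, seed)` — all random effects are drawn as a single seeded
block — and each subject's closed-loop noise stream is seeded from the trial
seed and the subject index, so results do not depend on evaluation order.

# The open-loop TCI algorithm

The classic TCI scheme is a reach-and-hold policy computed against the
population model only. The package implements it as one uniform
receding-horizon rate law, applied at every control interval (default 10 s):

* **Plasma targeting.** Over one interval the predicted $C_1$ is affine in
  the rate, $C_1(t+\Delta) = a + bU$, so the rate that lands exactly on
  target is $(T - a)/b$, clipped to $[0, U_{max}]$ — which also yields the
  standard behavior of shutting off while the prediction is above target.
* **Effect-site targeting.** The predicted *future peak* of $C_4$ (rate $U$
  for one interval, zero afterwards) is monotone in $U$; the rate is chosen
  by root finding so that the peak equals the target. Early in induction the
  solution saturates at $U_{max}$ (a full-rate loading pulse); the final
  pulse is trimmed so the predicted peak touches the target exactly (no
  overshoot by construction); afterwards the same rule produces maintenance
  rates that pin the predicted peak at the target, converging on the
  steady-state rate $U = CL \cdot T$.

The peak search scans a fixed 0.02-min grid over a horizon of five
effect-site half-lives with parabolic refinement around the grid maximum;
root finding uses a tolerance of $10^{-6}$ of the target. On the reference
model this holds $C_4$ within 0.03% of a 6 mg/L setpoint after
equilibration — comfortably inside the 1% specification used in the tests.

The per-interval formulation was chosen over a one-shot
"bolus-duration bisection then plasma tracking" construction because it
needs no mode switching, behaves identically (full-rate pulse, trimmed
final step, maintenance), and — crucially — is *the same function* the
closed-loop controller applies to its personalized model, which gives the
no-information equivalence (closed loop ≡ open loop when nothing has been
learned) by construction rather than by coincidence.

# The sensor

Measurements are taken every `period` seconds (default 30 s, first sample at
one period), corrupted by the residual-error model, and become usable only
`delay` seconds later (default 15 s). The default timing follows the running
description of the scenario; the alternative timing seen elsewhere in the
source material (period 15 s, delay 30 s) is one config edit away. Negative
noisy readings are delivered as-is — they are raw sensor output, and
clipping is a consumer decision.

Out-of-distribution failures are off by default (the baseline scenario has
none) but can be injected per sample with probability $p$ as spikes
(multiplicative), dropouts (zero) or stuck values (previous reading), each
flagged so downstream consumers can choose to down-weight them.

# The closed-loop controller

The controller keeps a posterior-mode estimate $\hat\eta$ of the subject's
random effects, refreshed whenever a measurement becomes available:

$$\hat\eta = \arg\min_\eta\;
  \sum_n \frac{\bigl(Y_n - C_1(t_n;\, PAR\,e^{\eta},\, U_{hist})\bigr)^2}
              {prop^2 C_1^2 + add^2}
  \;+\; \sum_k \frac{\eta_k^2}{\omega_k^2},$$

i.e. MAP estimation under the log-normal population prior and the combined
error likelihood, over exactly the parameters the population declares
variable ($\omega_k > 0$). Minimization is quasi-Newton (L-BFGS-B) warm
started from the previous estimate, with box bounds
$|\eta_k| \le 5\omega_k$ so a wild reading cannot drive the estimate to
infinity; if the optimizer fails the previous estimate is retained with a
warning. When both error terms are zero the fit degenerates gracefully to
unweighted least squares. Failure-flagged readings are included by default
(a documented switch excludes them).

The rate law is the TCI planner evaluated on the personalized model
$PAR\,e^{\hat\eta}$ and the controller's own state reconstruction (the
infusion history replayed through the personalized model — the controller
never peeks at the subject's true state). Rates are replanned at every
control interval and additionally whenever an update actually moves
$\hat\eta$. Causality is structural: the event loop only admits a
measurement into the buffer once the wall clock passes its availability
time, and the event log records, for every rate change, the newest
availability time in use — audited in the tests.

With a 15-minute trial and 30-second sampling the estimator sees ~29
measurements; clearance and central volume are well identified, slow
peripheral exchange only partially — which is the realistic regime: the
closed loop narrows the cohort band substantially without being able to
collapse it.

# Actuator and alarms

The actuator clips rates to $[0, U_{max}]$, optionally quantizes them,
depletes a finite syringe (delivery truncates mid-interval when the
reservoir empties, with an `EMPTY` alarm and zero delivery thereafter), and
raises `SATURATED`, `LOW_RESERVOIR` and `NEGATIVE_REQUEST` alarms into the
shared event log. There is no defensible universal physiological maximum
rate, so `max_rate` is a required configuration value; the shipped scenario
uses 200 mg/min (a 1200 mL/h pump ceiling at 10 mg/mL). Refills are modeled
as explicit scenario events and default to none.

# The trial engine and its statistics

`run_trial()` generates the cohort once, computes the open-loop schedule
once from the population means and administers it to every subject, and runs
each subject through the closed loop with its own seeded noise stream. Both
arms use the same actuation granularity (the TCI control interval) so that
their trajectories are comparable. Per-subject failures are caught, flagged
and excluded from summaries rather than aborting the trial.

Summaries are pointwise empirical medians and 2.5/97.5 percentiles
(`quantile` type 7, the linear-interpolation convention — the estimator
choice is documented because no canonical one exists). The accuracy metrics
over the equilibrated window (default: the second half of the trial, since
no canonical equilibration time exists either) are the PI95 band area
$\int (\mathrm{hi} - \mathrm{lo})\,dt$, the fraction of subjects within
±10% of target throughout the window, the maximum relative deviation from
the population prediction, and a configurable ±20% under-/over-dosing flag
list.

# What the generator does and does not emulate

The synthetic cohort reproduces: log-normal between-subject spread at
published magnitudes, combined-model measurement noise, sparse delayed
sampling, device saturation and finite reservoirs. It does not reproduce:
parameter correlations (etas are independent), time-varying physiology
(hemodynamic drift, blood loss), model misspecification (the controller's
structural model is the truth's structural model — only parameters differ),
pharmacodynamics (no concentration–effect link), or sensor hardware physics.
Passing trials here therefore demonstrate *algorithmic* superiority of
personalization under the stated variability model, not clinical
performance; structural-mismatch robustness would need a second, different
truth model, which the pluggable estimator/rate-law seams are designed to
accommodate.

# Problem sizes and runtime choices

The test suite exercises the full 1,000-subject open-loop dispersion
scenario directly; closed-loop cohort comparisons run at n = 100 over three
seed replicates with the 15-minute trial (a closed-loop subject costs just
under a second; the exact propagator keeps a full replicate at about a
minute and a half). Distribution-recovery checks use $10^4$ subjects and
$10^5$ residual draws, with Monte-Carlo tolerances stated as multiples of
the analytic standard errors rather than round numbers.

# Known limitations

* Two closed-loop controller *variants* are anticipated by the comparison
  design but only one canonical controller (MAP-personalized TCI) is
  implemented; the estimator and rate law are pluggable function arguments.
* The MAP objective weights residuals by the model-predicted concentration,
  which is the standard approximation; a full log-normal residual model or
  an importance-weighted posterior would change small-sample behavior.
* Effect-site targeting assumes $k_{e0}$ is known at its population value in
  the scenario configuration ($\omega_{ke0} = 0$); estimating $k_{e0}$ from
  plasma data alone is ill-posed without effect measurements.
* The open-loop arm uses the same parameter set the cohort was generated
  from; there is no "model family mismatch" arm.
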