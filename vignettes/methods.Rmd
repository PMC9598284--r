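---
title: "Methods: minimal CNS PBPK modelling with cnspbpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimal CNS PBPK modelling with cnspbpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cnspbpk)
```

## The model

`cnspbpk` implements a minimal physiologically based pharmacokinetic
(PBPK) model for unbound drug distribution from blood into the brain.
Six amounts are tracked: blood, a lumped peripheral tissue, the brain
vasculature, brain extracellular fluid (ECF), cranial cerebrospinal
fluid (CSF), and an absorbing external ventricular drain (EVD)
collection bag. In concentration form the circulating states obey

$$
\begin{aligned}
V_B \frac{dC_B}{dt} &= \mathrm{In}(t)
  + f_d \, CO \, \frac{C_T}{K_p}
  + Q_{br} C_{BV}
  - C_B \left( f_d\, CO + Q_{br} + CL \right) \\
V_T \frac{dC_T}{dt} &= f_d \, CO \left( C_B - \frac{C_T}{K_p} \right) \\
V_{BV} \frac{dC_{BV}}{dt} &= Q_{br} C_B + PS_{ECF} C_{ECF}
  + \left( PS_{CSF} + Q_{sink} \right) C_{CSF}
  - C_{BV} \left( Q_{br} + PS_{ECF} + PS_{CSF} \right) \\
V_{ECF} \frac{dC_{ECF}}{dt} &= PS_{ECF} C_{BV}
  - C_{ECF} \left( PS_{ECF} + Q_{bulk} \right) \\
V_{CSF} \frac{dC_{CSF}}{dt} &= PS_{CSF} C_{BV} + Q_{bulk} C_{ECF}
  - C_{CSF} \left( PS_{CSF} + Q_{sink} + Q_{EVD} \right) \\
\frac{dA_{EVD}}{dt} &= Q_{EVD} \, C_{CSF}
\end{aligned}
$$

with an intermittent-infusion input $\mathrm{In}(t)$. All
concentrations are unbound. The drain is assumed to compensate blocked
CSF reabsorption, so the effective sink flow is
$Q_{sink} = \max(Q_{sink}^{physio} - Q_{EVD},\, 0)$
(`effective_sink_flow()`). Because both the barrier backflux and the
sink return drug to the brain vasculature, the system conserves mass
exactly when $CL = Q_{EVD} = 0$; the unit tests assert this to 1e-9.

Patient physiology is reduced to body weight: the lumped tissue volume
closes the whole-body volume balance
(`derive_patient_physiology()`), and the flow-fraction constraint
$f_d + Q_{br}/CO \le 1$ is enforced.

## Exact simulation

The system is linear with piecewise-constant coefficients (infusion
on/off, drain-interval boundaries). `simulate_pbpk()` therefore
propagates the state with a matrix exponential per segment instead of
an adaptive ODE solver; the only numerical error is that of `expm`
itself. The state is augmented with running integrals
$\int A_B\,dt$, $\int A_{ECF}\,dt$, $\int A_{CSF}\,dt$, which makes
interval-averaged observations and AUCs analytic rather than grid
quadrature. The test suite cross-checks trajectories against an
independent `deSolve` transcription of the equations above
(agreement to 1e-6 relative) and the interval averages against
adaptive quadrature.

Steady state under a regimen of period $\tau$ is obtained from the
periodicity condition $x(\tau) = x(0)$, a linear solve in the five
circulating states (`steady_state()`); a repeated-dosing fallback with
relative tolerance 1e-8 covers the (degenerate) singular case.

## Observation models

Three observation streams are supported (`read_pk_dataset()`):

* `plasma_unbound` — point samples of $C_B$;
* `dialysate` — recovery-corrected microdialysate over a collection
  interval $[t_1, t_2]$, modelled as the **time average** of
  $C_{ECF}$ over the interval,
  $\frac{1}{t_2 - t_1}\int_{t_1}^{t_2} C_{ECF}\,dt$
  (`dialysate_prediction()`). An instantaneous-concentration or
  un-normalised integral reading of a dialysate sample is
  dimensionally inconsistent with a pooled fraction; the time average
  is the standard interpretation and is what the generator and the
  likelihood both use;
* `evd` — drained CSF pooled in the collection bag,
  $Q_{EVD}\int_{t_1}^{t_2} C_{CSF}\,dt / V_{EVD}$
  (`evd_prediction()`), which reduces to the time average of
  $C_{CSF}$ when the sampled volume matches $Q_{EVD}(t_2-t_1)$;
  `evd_schedule()` warns when it does not (within a 20% tolerance).

## Population estimation

`fit_population()` maximises a Laplace-approximated marginal
likelihood — the standard conditional-estimation approach for sparse
PK data. Between-subject variability is log-normal on clearance only,
$CL_i = CL\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$; residual error
is combined (proportional + additive) for plasma and proportional for
the CNS streams. For each subject the empirical-Bayes mode
$\hat\eta_i$ is found by a safeguarded finite-difference Newton search
in compiled code, and the subject's contribution is
$h(\hat\eta_i) + \log\omega + \tfrac12\log H_i$ with $H_i$ the
curvature at the mode. The unit tests verify this approximation
against adaptive quadrature of the exact one-dimensional marginal
(agreement within 1%).

Fixed quantities follow the identifiability of the design: $f_d$ is
fixed (it sits at the maximum the flow-fraction constraint allows) and
the barrier clearances $PS_{ECF}$, $PS_{CSF}$ are fixed to their
in silico values unless `estimate_PS = TRUE`.

### Optimiser choices

The outer problem is solved by Nelder–Mead on log-transformed
parameters. A gradient-based quasi-Newton outer loop is unreliable
here: the objective is evaluated with warm-started inner modes, which
makes it slightly history-dependent, and that noise swamps
finite-difference gradient steps. The fit triages `n_restarts`
jittered starts with short runs, then polishes the best one to
convergence, warm-starting the polish from that run's own
empirical-Bayes modes. Plausibility boxes (e.g. $\omega \le 4$) keep
the search out of a degenerate region where an inflated $\omega$ lets
the random effects absorb any fixed-effect misfit. In
`estimate_PS` mode the restarts additionally spread the PS starting
values over decades, because the likelihood is flat in PS once barrier
exchange becomes perfusion-limited.

Starting values are data-driven where cheap (clearance from a naive
pooled dose/AUC estimate) and neutral otherwise ($K_p = 1$,
$\omega = 0.3$, sigmas 0.2/0.5). Convergence uses `optim`'s relative
tolerance (default 1e-8) with an iteration cap.

Uncertainty is by nonparametric subject-level bootstrap
(`bootstrap_ci()`), which suits the small-cohort setting and makes no
curvature assumptions.

## Synthetic cohorts

`generate_cohort()` emulates a sparse neuro-ICU sampling design: 500
mg infused over 30 min every 8 h to steady state; 7–13 plasma samples
per subject drawn from clinically plausible times; CNS fractions
collected over 0.5-h intervals to 3 h and 1-h intervals to 8 h; half
the cohort monitored by microdialysis (ECF) and half by an EVD (CSF)
with per-interval drain flows drawn from 0.001–0.04 L/h; body weights
uniform on 75–115 kg. The generating distributions use
`population_truth()` (log-normal IIV on CL, the same residual models
as the likelihood), so generator and estimator agree by construction —
misspecification studies can perturb either side. Everything is
reproducible from a single seed.

Realism limitations, stated plainly: residual errors are Gaussian and
uncorrelated; dropout, missed samples, assay limits of quantification
and time-varying drain flows within an interval are not simulated; IIV
is on CL only.

## Diagnostics

`vpc()` simulates replicate cohorts at the exact observed design (same
subjects, times, drain flows, weights), summarising 5/50/95 percentile
bands per stream and time; `vpc_coverage()` reports the fraction of
observations inside the 90% band (≈0.9 for a well-specified model).
`gof_table()` reports observed/predicted pairs and per-subject
interval-AUC fold errors with geometric-mean summaries per stream.

## Sensitivity analyses

`sweep_pathophysiology()` varies exactly one parameter at a time over
pathophysiologically motivated ranges — barrier permeability ×1–5
(injury), ECF volume ×1–1.4 (oedema), cerebral blood flow ×0.2–1
(hypoperfusion) — and reports single-dose ECF/CSF AUC deviations from
baseline. `sweep_evd()` grids the drain flow (0–0.04 L/h) through the
sink coupling. For a high-permeability drug such as the reference
parameterisation, CNS exposure is insensitive (<5% deviation)
across all sweeps; for a low-permeability drug
(`low_permeability_drug()`), permeability scaling and drain flow both
matter, in the expected directions.

## Problem sizes and tolerances

Package choices, selected for a single-CPU budget: recovery
experiments use 8-subject cohorts (20 replicates) for CL and $K_p$ and
50-subject cohorts for $\omega$; VPCs default to 1000 replicates;
bootstrap defaults to 200 refits. Matrix-exponential agreement with
the ODE oracle is asserted at 1e-6 relative, interval averages at
1e-8, mass balance at 1e-9, and the Laplace-vs-quadrature check at 1%.
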