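---
title: "Modelling CTL control of a transplanted melanoma: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CTL control of a transplanted melanoma: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`actdyn` quantifies how adoptively transferred cytotoxic T lymphocytes (CTLs)
control a B16F10 mouse melanoma, and how agonist anti-CD137 costimulation
changes that control. The package couples a small mechanistic ODE model to
two kinds of observations: caliper-style tumour-volume series, and intravital
two-photon records in which cells and their mitosis/apoptosis events are
counted in small imaging fields over 1–3 hour windows. This vignette
documents the model, the statistical machinery around it, and the design
choices made where more than one reasonable implementation existed.

## The dynamical model

Five state variables describe one tumour: proliferating tumour cells $T_p$,
quiescent tumour cells $T_q$ (with total $T = T_p + T_q$), intratumoural
CTLs $E$, and two slow variables that set CTL turnover — an induction level
$I$ (the per-CTL mitosis rate, day$^{-1}$) and a resistance level $R$ (the
per-CTL apoptosis rate, day$^{-1}$):

$$
\begin{aligned}
\frac{dT_p}{dt} &= g\,T_p - (k_e + k_q)\,\frac{T_p}{T}E + d_q T_q, \\
\frac{dT_q}{dt} &= k_q\,\frac{T_p}{T}E - k_e\,\frac{T_q}{T}E - d_q T_q, \\
\frac{dE}{dt}  &= s\,T^{2/3} + E\,(I - R), \\
\frac{dI}{dt}  &= k_i\,\frac{E}{T} - d_i I, \qquad
\frac{dR}{dt}  = k_r\,\frac{E}{T} - d_r R.
\end{aligned}
$$

The modelling assumptions, in brief:

* **Exponential baseline growth.** Over the two-week experiment the tumours
  stay small (well under 1 mm³ median), so no carrying capacity is needed;
  tumour cells divide at a constant rate $g$, fixed at 0.5 day$^{-1}$
  (doubling time 1.4 days) from untreated growth before any fitting.
* **Constant per-CTL killing.** A general killing law saturating in both
  effectors and targets reduces, in the regime of dense tumour cells and
  sparse CTLs, to a constant per-CTL rate $k_e$ (CTL$^{-1}$ day$^{-1}$). The
  saturation constants themselves are not identifiable from these data and
  are not free parameters. The flip side is that the model is only trusted
  while tumour cells are plentiful.
* **Killing is shared between compartments** in proportion to their
  frequency ($T_p/T$ and $T_q/T$), so the quiescence exchange cancels from
  the total and $dT/dt = g\,T_p - k_e E$ exactly. This identity is used as a
  test oracle throughout.
* **Antiproliferative effect as a reversible quiescent state.** CTLs push
  tumour cells out of cycle at rate $k_q$ per CTL (an IFN-γ-type cytostatic
  effect); cells recover at $d_q$.
* **Boundary-limited infiltration.** CTLs enter at a constant rate $s$ per
  unit boundary area of an approximately spherical tumour, hence the
  $T^{2/3}$ term. Before the transfer day there are no transferred CTLs to
  infiltrate, so $s$ is inactive until then.
* **Slow CTL turnover loops.** Both $I$ and $R$ are driven by the E:T ratio:
  the frequency of CTLs among tumour cells determines both the auto-inductive
  proliferation stimulus and the tumour's acquired resistance (increased CTL
  apoptosis). $d_r$ defaults to 0 — over this short experiment resistance
  shows no measurable decay, and freeing it yields values indistinguishable
  from zero.

Simulations start at inoculation (day 0) from $T_p = 1200$, all other states
zero. Two calibrated parameter sets ship with the package
(`act_only_params()`, `act_mab_params()`); the fitted contrast is that
costimulation raises the antiproliferative rate ($k_q$: 41.2 vs 9.2) and the
E:T trajectory, while per-capita killing is, if anything, slightly lower
(0.5 vs 0.75 CTL$^{-1}$ day$^{-1}$).

## Numerical integration

`simulate_model()` integrates the system with `deSolve`'s `lsoda`
(compiled right-hand side, `rtol = atol = 1e-8`). Two choices matter:

* **The transfer day is a breakpoint, not a discontinuity.** The step
  activation of $s$ is handled by splitting the integration at the transfer
  day and restarting the solver, because adaptive steppers handle
  discontinuous right-hand sides poorly.
* **Extinction is ramped, not cut off.** The per-tumour-cell terms use
  $T_x/\max(T,1)$ and $E\,T/\max(T,1)^2$: identical to $T_x/T$ and $E/T$
  whenever at least one cell remains, and decaying continuously to zero
  below that. A hard cutoff at $T = 1$ makes the right-hand side
  discontinuous exactly where aggressive scenarios (e.g. quadrupled
  quiescence induction) eradicate the tumour, and stalls the integrator
  there; the ramp keeps extinction absorbing and the solver stable without
  touching any fitted regime. The solver is not told about the model's
  non-negativity, so outputs are floored at zero to remove tolerance-level
  undershoot.

The solver and tolerances are this package's choice; nothing in the data
constrains them, and the suite checks self-convergence (refined grid and
tolerances agree to better than $10^{-4}$ relative) plus closed-form limits
(pure exponential growth; the constant-CTL linear regime).

## From data to calibration points

All fitting happens in the common currency of *calibration points*, each a
scalar with a kind, a day and a condition tag, in day$^{-1}$ (except the
dimensionless E:T ratio):

* **Volumetric growth rates**: $\ln(V_2/V_1)/(t_2 - t_1)$ for successive
  volume pairs, placed at the interval midpoint. Points retain their
  interval bounds.
* **Intravital process rates** per imaged position: killing
  $=$ TC apoptosis events / (time × CTLs); TC mitosis $=$ mitosis events /
  (time × tumour cells); CTL mitosis and apoptosis per CTL; E:T
  $=$ CTL count / TC count. Durations are hours; rates are converted to
  day$^{-1}$. A position with no CTLs yields *no* per-CTL points — a 0/0
  rate is uninformative and recording it as zero would bias a fit.
* **Model-side counterparts**: killing $= k_e$; TC mitosis $= g\,T_p/T$;
  CTL mitosis $= I$; CTL apoptosis $= R$; E:T $= E/T$; net growth
  $= (g\,T_p - k_e E)/T$.

One deliberate asymmetry: `model_predictions()` reports the *instantaneous*
model growth rate (the model is smooth, so finite-differencing it for a
readout would only add error), but inside the RMSE objective the model is
compared to a growth-rate datum by log-differencing the model's $T(t)$ over
*the same measurement interval* that produced the datum. Comparing an
interval-averaged datum to a midpoint-instantaneous prediction leaves a
systematic residual wherever the dynamics bend quickly (right after
transfer, when $k_q$ is large, the two differ by ~0.1 day$^{-1}$), which
would bias the fit away from the generating parameters; like-for-like
differencing makes the objective exactly zero at self-consistency.

The absolute cell counts per field are deliberately discarded in favour of
the E:T ratio: field counts depend strongly on where the imaging window
lands, while the ratio does not inherit the field's physical size.

## Poisson killing models

Per position, the number of TC apoptosis events is modelled as Poisson with
intensity either proportional to the CTL count ("linear", rate per CTL-day)
or to the product of CTL and tumour-cell counts ("mass action"). The
imaging duration enters as the exposure; whether one normalises counts per
hour first or includes duration in the exposure changes no ranking, and the
explicit exposure is used. MLEs are closed-form (total events over total
exposure) and the suite verifies them against an independent numerical
maximisation to $10^{-8}$. Fits pooled over all positions or with one rate
per treatment group are ranked by AIC and BIC; on cohorts simulated from
the linear intensity with five-fold variation in tumour-cell counts, AIC
recovers the linear model in well over 90% of replicates, mirroring the
finding that killing shows no detectable dependence on tumour-cell numbers.
`poisson_band()` provides the expectation line and exact inverse-CDF
Poisson quantiles (counts are small; a normal band would be wrong).

## Calibration

The objective is the plain RMSE over all calibration points of a condition
group, both transfer schedules (day 3 and day 7) simulated with one shared
parameter set. Rate-kind residuals and E:T residuals are pooled unweighted:
the data were converted to a common day$^{-1}$ scale precisely so that this
is meaningful, and the dimensionless E:T points are listed among the fitted
data, so they enter the same pool (a per-kind weight hook exists but
defaults to off — excluding E:T is a one-line filter on the points). Points
from untreated conditions do not enter: $g$ is fixed from them beforehand.
Integration failures inside the objective return a finite $10^6$ penalty so
the optimiser can keep moving through pathological corners of the box.

Minimisation uses differential evolution with the local-to-best mutation
(`de_optimize()`): each member moves towards the current best plus a scaled
random difference, with binomial crossover and greedy replacement, so the
best objective value is non-increasing by construction. Search bounds are
0–50 day$^{-1}$ for the rate constants and 0–5 for $s$; defaults are
population 200, 500 generations, 5 independently seeded repeats. `F = 0.8`
and `CR = 0.9` are standard settings for this strategy and are exposed in
`fit_config()`. All randomness flows from one master seed, so a fit is
exactly reproducible.

The package's self-checks run a reduced budget (population 40, 120
generations, 3 repeats) against a noise-free synthetic cohort generated at
the calibrated ACT+mAb values: the refit lands within a few percent of the
generating $k_q$ and $s$ with RMSE $\sim 10^{-4}$, and noisy cohorts at the
default noise model recover the identifiable parameters ($s$, $k_e$, $k_q$,
$d_q$) within two-fold in the large majority of replicates. The weakly
identified induction pair ($k_i$, $d_i$) is judged by objective value only —
with two days of intravital sampling, many $(k_i, d_i)$ pairs produce nearly
identical CTL-mitosis trajectories. `local_sensitivity()` quantifies how a
±20% perturbation of each parameter degrades the fit.

## The synthetic cohort generator

No raw imaging dataset is distributed, so `generate_cohort()` emulates the
study design: volumes on days 1, 3, 6, 9, 13, 15 for every mouse; transfer
on day 3 or 7; four positions per mouse imaged 1–3 h on days 6 and 9 (only
on days at or after transfer — for day-7 transfer only day 9 qualifies);
four mice per condition by default, a compromise typical of intravital
work. The noise model:

* volumes: $T(\text{day})/\rho$ times lognormal noise with CV 0.2, where
  $\rho = 1.3\times10^5$ cells mm$^{-3}$ places the untreated day-3 volume
  at the observed median of 0.04 mm³ given 1200 inoculated cells ($\rho$ is
  a bookkeeping constant, not a density estimate);
* field cell counts: Poisson around an expectation proportional to tumour
  size, multiplied by a lognormal field factor ($\sigma = 0.5$) reflecting
  how strongly counts depend on where the window lands (the reference field
  holds ~1600 cells, the field volume times $\rho$, at the day-6 untreated
  tumour size);
* CTL counts: Poisson with mean $n_{tc}\,E/T$;
* event counts: Poisson with means (per-capita model rate) × count ×
  duration, the same distributional assumption the killing analysis makes
  for apoptosis, extended to all four event types for coherence.

With `noise = FALSE` every draw is replaced by its expectation (counts stay
non-integer), giving cohorts from which the observation layer recovers the
model's rates *exactly* — the round-trip oracle used by the calibration
tests. Per-mouse parameter jitter is deliberately absent by default: true
between-mouse variability is unknown, and adding it would blur the
parameter-recovery contract the generator exists to test. What passing
tests on these cohorts demonstrate is therefore internal consistency of the
pipeline under the stated noise model — not robustness to features real
data may have (spatial heterogeneity within tumours, non-Poisson event
clumping, measurement error in cell identification, between-mouse biology).

## Scenario analysis

`scale_sweep()` multiplies $k_e$ or $k_q$ by factors (default 0, 1, 3, 4)
and re-simulates; `burden_summary()` reduces each trajectory to the final
total cell count and the area under $\log T$. At either calibrated optimum,
abrogating killing ($k_e \times 0$) raises the day-15 burden by less than
two-fold, while abrogating quiescence induction ($k_q \times 0$) raises it
by one to two orders of magnitude — the antiproliferative effect, not
cytolysis, carries tumour control, and the effect is stronger for the
costimulated parameter set. Increasing the killing factor monotonically
improves control. `condition_report()` tabulates the fitted process rates,
E:T ratio and net growth for one condition over time; the costimulated set
sustains a visibly higher E:T ratio at late times after transfer.

## Problem sizes used in the packaged checks

The shipped test-suite and acceptance script scale the experiments to:
1000 random states for the conservation identity; 100 random datasets for
the MLE oracle; 100 replicates of 200 positions for model selection; one
noise-free two-schedule cohort (70 points) refitted at population 40 / 120
generations / 3 repeats; five noisy replicates at population 24 / 60
generations for stochastic recovery; 20-mouse cohorts for the stochastic
round trips. These sizes are the package's own choice of a thorough but
quick regression battery; the full-budget fit remains available through
`fit_config()` defaults.

## Known limitations

* No spatial structure: the tumour is well mixed, so border effects,
  CTL-migration differences and local density variation are invisible.
* The constant per-CTL killing term overstates killing when the tumour has
  regressed to small sizes (the saturation it replaces would throttle it).
* No endogenous immune compartment; only transferred CTLs are modelled.
* The induction/resistance variables are phenomenological summaries of CTL
  turnover, not mechanistic species; only their products with $E$ are
  observable, and $(k_i, d_i)$ are correspondingly weakly identified.
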