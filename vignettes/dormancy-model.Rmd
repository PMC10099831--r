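---
title: "Modelling active and dormant microbial biomass across freeze-thaw transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling active and dormant microbial biomass across freeze-thaw transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodorm)
```

## The problem

Microbial communities on glacier surfaces are repeatedly pushed across the
freezing point. Dormancy — a reversible state with zero reproduction and a
reduced maintenance demand — lets cells persist through frozen periods and
reactivate when melt returns. `cryodorm` implements a minimal process-based
description of this: two biomass pools (active *B₁*, dormant *B₂*) coupled
to a dissolved organic carbon pool (*DOC*), with temperature as the single
environmental driver of the state change.

## Model structure and assumptions

Only heterotrophic bacteria are represented; all catabolic energy derives
from DOC. The governing system (time in hours, pools in μg C L⁻¹):

$$\frac{dB_1}{dt} = V_{B1} - D_{B1} - \xi + \epsilon, \qquad
  \frac{dB_2}{dt} = -D_{B2} + \xi - \epsilon,$$
$$\frac{dDOC}{dt} = -\frac{V_{B1}}{Y} - (M_{B1} + M_{B2}) + (D_{B1} + D_{B2}).$$

* **Growth** is Michaelis–Menten on DOC and restricted to the active pool:
  $V_{B1} = B_1\, v_{max}\, DOC/(K_v + DOC)$. Total carbon uptake is
  $V_{B1}/Y$; the non-yield share is respired.
* **Mortality** is first order, $D_{Bn} = \alpha_{Bn} B_n$, with dormant
  cells dying more slowly. All necromass carbon returns to DOC — there is
  no humification or export.
* **Maintenance** is a proportional carbon cost for both pools,
  $M_{Bn} = m_{Bn} B_n$, drawn from DOC and respired; dormancy lowers but
  does not abolish it.
* **State switching** is bidirectional and temperature-controlled:
  deactivation $\xi = (1-\theta_S) R_{S,D} B_1$ and activation
  $\epsilon = \theta_S R_{S,A} B_2$, with the Fermi–Dirac-form sigmoid
  $$\theta_S(T) = \frac{1}{\exp\!\big((-T + K_S)/(st_S K_S)\big) + 1},$$
  which equals 0.5 exactly at the threshold temperature $K_S$ and increases
  strictly with temperature. Below $K_S$ deactivation dominates; above it
  activation does. Substrate- or energy-dependent switching, multiple
  guilds, phototrophs, and melt/albedo feedbacks are out of scope.

A cumulative CO₂ pool is carried as a pure diagnostic, never feeding back,
so that the carbon budget closes identically:
$dB_1 + dB_2 + dDOC + dCO_2 = 0$ at every state. The test suite checks this
to machine precision pointwise and to $<10^{-6}$ relative drift along
trajectories.

## Parameters, defaults, and why

| name | meaning | unit | default |
|---|---|---|---|
| `v_max` | maximum growth rate of active biomass | h⁻¹ | 0.00347 |
| `K_v` | half-saturation DOC for growth | μg C L⁻¹ | 100 |
| `Y` | growth yield | – | 0.6 |
| `alpha_B1` | mortality of active biomass | h⁻¹ | 1e-3 |
| `alpha_B2` | mortality of dormant biomass | h⁻¹ | 1e-4 |
| `m_B1` | maintenance of active biomass | h⁻¹ | 2e-3 |
| `m_B2` | maintenance of dormant biomass | h⁻¹ | 5e-4 |
| `R_SD` | specific deactivation rate | h⁻¹ | 0.045 |
| `R_SA` | specific activation rate | h⁻¹ | 0.0403 |
| `K_S` | switching threshold temperature | °C | 0.1 |
| `st_S` | switch steepness (dimensionless) | – | 2 |

The defaults are a **repository calibration**: they reproduce the reference
scenario behaviour of a glacier-surface community — a majority (>60%)
dormant within 24 h of freezing at −3 °C with under 1% active beyond day 5;
55% reactivated within a day of thaw at 0.5 °C with biomass growing from
0.55 to 0.83 μg C L⁻¹ over ten days; and frozen-period catabolism dominated
by maintenance of the dormant pool rather than growth. The scenario-driving
pair (`v_max`, `R_SA`) was fitted to the day-1 activity and day-10 biomass
readouts by Newton iteration; `R_SD` follows from the freeze-side decay
(active fraction ≈ e^(−R_SD t) when θ≈0); `Y` and `m_B2` are pinned by the
catabolism partition, which they control without affecting the biomass
trajectories at all. `K_S = 0.1` °C places the threshold between the two
scenario temperatures with θ(0.5 °C) ≈ 0.88 and θ(−3 °C) ≈ 2e-7; `K_v = 100`
keeps growth near (DOC-)saturation at the 1200 μg C L⁻¹ initial condition,
so the scenarios probe the switching dynamics rather than substrate
limitation. Mortality constants give mean lifetimes of ~40 days (active)
and ~14 months (dormant), within the range expected for cold-adapted
communities. Every default is overridable per call or from a flat
key–value parameter file (`read_params()`).

The implied doubling time at saturation, ln 2 / `v_max` ≈ 8 days, is slow
but deliberate: it is what sustained net growth of a just-thawed community
at 0.5 °C looks like once mortality is paid.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`
  (configurable). The forcing is piecewise constant, so integration
  restarts at every temperature-segment boundary; no internal step ever
  straddles a discontinuity. Output is on a uniform grid (default 1 h,
  241 points per 10-day scenario) that resolves the 24 h transitions.
* **Boundary convention.** Schedules are right-continuous: a segment's
  temperature applies from its start instant inclusive. "Day *n*" readouts
  are evaluated at exactly *t* = 24 *n* h.
* **Verification oracle.** `oracle_integrate()` is a hand-written
  fixed-step classical RK4 over the same derivative function, sharing no
  stepping code with the adaptive route; the suite requires agreement
  within 1e-4 relative on all presets at dt = 0.005 h.
* **Degenerate inputs.** Integrator round-off below zero is clamped at a
  1e-12 tolerance; larger negative excursions raise an error. The sigmoid
  saturates to exactly 0/1 in floating point far from `K_S`; inside the
  flux laws it is nudged to the open interval at the 1e-15 level. A smooth
  limitation factor `DOC/(DOC + 1e-6)` on growth and maintenance prevents
  DOC from being driven negative under extreme starvation (a warning is
  emitted if DOC nears exhaustion); at scenario DOC levels the factor is
  1 − 8e-10 and numerically invisible. The switch scale `st_S · K_S` must
  be strictly positive — a negative threshold temperature is allowed only
  with a matching-sign steepness — validated at parameter load, because the
  printed sigmoid inverts otherwise.
* **Cumulative summaries** (growth uptake vs maintenance partition) use
  trapezoidal integration of the stored flux series; halving the output
  step changes no reported summary beyond 1e-5 relative.

## The BONCAT statistics module

Empirical activity data arrive as per-field-of-view counts of DAPI-stained
(all) and BONCAT-positive (translationally active) cells. The module treats
the **per-field fraction** `boncat/dapi` as the observation unit — matching
the replicate/field structure of such campaigns — and reports grouped means
with sample SD; groups under 20 fields are flagged as below the usual
counting convention. Replicate and habitat contrasts use the classical
equal-variance one-way ANOVA (via `stats::lm`), with degenerate inputs
(zero within-group variance) resolved explicitly. Fields with zero DAPI
cells have an undefined fraction and are excluded with a logged count.

Whether such campaigns test per-field fractions or per-replicate means is
rarely stated; the per-field choice here is an explicit assumption of this
package.

### The synthetic generator

`simulate_counts()` emulates a count campaign: per-field totals are Poisson
(`mean_cells_per_fov`), positives are beta-binomial around `true_fraction`
with beta shapes `p/od` and `(1-p)/od`, so `overdispersion = 0` degenerates
to plain binomial and larger values widen the field-to-field spread the way
spatial patchiness does in real fields of view. It does **not** emulate:
counting error and double-staining ambiguity, per-replicate batch effects
beyond what overdispersion absorbs, algal autofluorescence (the schema is
bacteria-only), or any dependence between total cell number and activity.
Passing tests on synthetic tables therefore validate the estimator and test
machinery — recovery of the true fraction (bias < 0.01 at 10³ fields) and
correct ANOVA type-I calibration (empirical α within [0.035, 0.065] at the
nominal 0.05 over 2,000 null datasets) — not any claim about a particular
field campaign, whose raw counts are generally unpublished.

## Known limitations

* One guild, one substrate, temperature as the only driver: the model is a
  framework for exploring state-switching dynamics, not a site simulator.
* The switching sigmoid's scale couples `st_S` to `K_S` (scale
  `st_S · K_S`), so thresholds near 0 °C make the switch sharp unless
  `st_S` is raised; this is a property of the printed functional form.
* Scenario claims are anchored at daily readouts on a 1 h grid; sub-hourly
  forcing would need a finer output step (supported but untested against
  any reference).
* The calibrated defaults are one point in a degenerate solution space:
  other (`v_max`, `R_SA`, ...) combinations reproduce the same four
  readouts. Only the readouts themselves, not the individual constants,
  should be treated as constrained.

## Problem sizes used in the shipped checks

Scenario checks integrate 241-point, 10-day trajectories (<1 s each); the
oracle comparison uses RK4 at dt = 0.005 h (48,000 steps per scenario); the
statistics properties use 10³ fields for estimator bias and 2,000 simulated
three-group datasets (20 fields each) for ANOVA calibration — all chosen to
make the checks sharp at desk scale.
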