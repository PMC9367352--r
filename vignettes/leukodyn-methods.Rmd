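---
title: "Methods: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukodyn)
```

## The model and its assumptions

`leukodyn` simulates a three-compartment ODE system for a murine CLL model:
A20 leukemic cells $A$, immune effector cells $E$, and drug molecules $C$,
all as whole-animal amounts.

$$\frac{dA}{dt} = rA\left(1-\frac{A}{K}\right) - \mu_A A E
  - \mu_{AC}\,\frac{AC}{a + C}$$
$$\frac{dE}{dt} = -\mu_E E + \frac{pAE}{c+A} - \mu_{EA} A E
  - \mu_{EC}\,\frac{EC}{b+C}$$
$$\frac{dC}{dt} = \sum_{m} d\,\delta(t - t_m) - \mu_C C
  - \mu_{CA}\,\frac{CA}{a+A}$$

Assumptions worth making explicit:

* **Logistic tumor growth.** The intrinsic rate $r$ is measured from paired
  bleeds by the two-point formula $r = \ln(N_t/N_0)/\Delta t$; the capacity
  $K$ is a simulation-level constant, not measured.
* **Log-kill with saturation.** Chemotherapy removes a constant *fraction*
  of tumor cells per unit time while drug is abundant; the Michaelis–Menten
  factor $C/(a+C)$ switches the kill off as $C$ approaches the half-max
  amount $a$. With $a = 2\times10^3$ molecules against doses of
  $10^{13}$–$10^{15}$, the kill term is effectively all-or-nothing in time:
  what a dose buys is *duration* of full-strength kill, roughly
  $\ln(d/a)/(\mu_C + \mu_{CA})$ hours. This single mechanism explains the
  qualitative pattern the package reproduces — strong dose-dependence for
  cytarabine (low dose = short coverage) and near dose-insensitivity for
  ibrutinib (doubling $d$ adds only $\ln 2 / \mu$ hours of coverage).
* **Impulsive dosing.** Administrations are instantaneous jumps of exactly
  $d$ molecules in $C$ ($A$, $E$ continuous). The Dirac comb is realized as
  exact state jumps — integration stops at each dose time, $d$ is added,
  integration restarts — never as a narrow smooth pulse, which would
  introduce stiffness artifacts.
* **One drug pool.** A single first-order elimination rate per drug
  ($\mu_C = \ln 2/t_{1/2}$); no compartments, no biphasic elimination.
* **The unit quirk in the clearance term** $C A/(a+A)$ — the half-max
  constant $a$ is a molecule amount added to a cell count — is kept as
  published rather than corrected; since $A \gg a$ throughout, the factor is
  ~1 and the term behaves as $\mu_{CA} C$.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `r` | tumor growth rate | 0.01 | 1/h |
| `K` | tumor carrying capacity | 4e6 | cells/mouse |
| `mu_A` | effector-on-tumor kill | 2e-12 | 1/h |
| `mu_AC` | drug-on-tumor kill (protocol specific) | 0.012 | 1/h |
| `a` | half-max drug amount (tumor effect) | 2e3 | molecules |
| `mu_E` | effector natural death | 4e-5 | 1/h |
| `p` | effector stimulation by tumor | 4e-14 | 1/h |
| `c` | half-max tumor count (immune stimulation) | 1e2 | cells |
| `mu_EA` | tumor-on-effector interaction | 4e-15 | 1/h |
| `mu_EC` | drug-on-effector mortality | 417 | 1/h |
| `b` | half-max drug amount (effector effect) | 5e6 | molecules |
| `mu_C` | drug chemical deactivation | 0.231 (Cyt), 0.116 (Ibr) | 1/h |
| `mu_CA` | drug consumption killing tumor | 10·`mu_AC` | 1/h |

Per-protocol calibrated kill rates: `cyt_low` 0.001, `cyt_high` 0.012,
`ibr_low` 0.0041, `ibr_high` 0.0042, combination 0.0161 (the sum of its
components). `mu_EC = 417`/h is far above every other rate and makes the
flow stiff whenever drug is present; it is used as published. Because
`mu_A`·E ≈ 5e-9/h at the default effector level, the immune compartment is
dynamically almost inert at these magnitudes — it is carried for structural
completeness, and its collapse under drug (at rate `mu_EC`) has no visible
effect on the tumor curve.

Initial conditions: $A(0) = 5\times10^4$, $E(0) = 2500$, $C(0) = 0$, with
$t = 0$ the start of treatment. The engraftment period before treatment is
not simulated.

## Dosing and readout conventions

These conventions are deliberate package choices and are applied uniformly:

* **Mouse mass 0.020 kg.** The published mg-per-mouse conversions
  (62.5 mg/kg → 1.25 mg; 18 mg/kg → 0.36 mg) imply exactly 20 g.
* **Rounded per-mg constants** (2.4e15/mg Cyt, 1.4e15/mg Ibr) are used for
  schedules so that the canonical dose amounts (3.0e15, 5.04e14, 3.252e15
  molecules) are reproduced exactly; `molecules_from_mass()` exposes the
  exact Avogadro arithmetic separately for auditing.
* **One administration per treatment day** at $t = 24(\text{day}-1)$ h;
  the first dose coincides with $t=0$.
* **Readout at Day 12** (288 h) for every arm, matching the experimental
  bleed day; configurable via `evaluation_day` / `t_eval`.
* **Combination regimen**: the combined per-dose amount (3.252e15
  molecules) is administered on each of days 1–5 and 8–10; the mixed decay
  rate is the molecule-fraction-weighted average (fractions rounded to
  0.92/0.08 to match the published arithmetic — `round_fractions = NULL`
  gives exact fractions), and the combined `mu_AC` is the sum of the
  single-drug rates with no interaction term.

### Sensitivity of the inhibition readout to these conventions

The percent-inhibition readout is strongly convention-dependent, and users
comparing against previously reported numbers should be aware of it. Under
the conventions above, `reproduce_table2()` computes 14.8 / 75.6 / 66.1 /
67.0 / 98.8 percent for the five arms, whereas the previously published
simulation figures for the same parameter values are 10 / 59 / 43.4 / 44 /
95. We investigated this gap systematically (including an independent
re-implementation of the integration in another language, which agrees with
this package to seven digits): no single dosing/readout convention —
per-course single bolus, per-block boluses, readout at end-of-course, or
any common fixed readout time — reproduces all five published values
simultaneously, while each value individually is attainable at *some*
readout time. The package therefore keeps one uniform, documented
convention and reports the discrepancy openly (`reproduce_table2()` flags
each arm) instead of tuning per-arm conventions. All *qualitative*
conclusions are insensitive to this choice: cytarabine's inhibition is
strongly dose-dependent, ibrutinib's is not (66.1 vs 67.0 at a doubled
dose), the combination is the strongest arm, and inhibition is monotone in
both `mu_AC` and dose.

## Numerics

* **Integrator.** `deSolve::lsoda` with automatic stiff/non-stiff
  switching. An explicit adaptive Runge–Kutta 4(5) was evaluated first but
  the 417/h effector-collapse rate forces stability-limited steps of
  ~0.007 h while drug is on board; `lsoda` handles the same segments in
  milliseconds. Accuracy is verified against two closed-form oracles
  (logistic growth to <1e-6 relative over 600 h; exponential drug decay to
  <1e-6) and by a refinement test (halving tolerances moves the Day-12
  tumor burden by <1e-4 relative).
* **Tolerances.** `rtol = 1e-10`; absolute tolerances per state:
  1e-2 cells for $A$ and $E$, 1 molecule for $C$. The tight $C$ tolerance
  matters: the kill term switches off when $C$ crosses $a = 2\times10^3$
  molecules, fifteen orders of magnitude below the post-dose level, and a
  loose absolute tolerance there visibly shifts the inhibition readout.
* **Negativity.** $E$ collapses to ~0 within minutes of a dose and the
  multistep solver can ring a fraction of a cell below zero while the
  state sits under the error-control floor. Excursions smaller than one
  cell ($A$, $E$) or 1e6 molecules ($C$; sub-ppm of any dose) are clamped
  to zero as sub-granularity round-off; anything larger raises an error
  rather than being silently absorbed.
* **Output grid.** Hourly samples plus a pre- and post-impulse row at every
  dose time, so jumps are explicit and `trajectory_state()` treats $C$ as
  right-continuous.

## Equilibria

Stability analysis is generic linearization: the hand-derived $3\times3$
Jacobian (validated against central finite differences) evaluated at each
fixed point, classified by eigenvalue real parts with a scale-aware
threshold $\varepsilon = 10^{-12}\max|\text{rate}|$. Root finding uses
exact branch reduction instead of a multidimensional solver: with $C$
fixed, $dE/dt = 0$ (for $E\neq0$) is one-dimensional in $A$ and is scanned
on a log grid for bracketed sign changes (`stats::uniroot`); $E$ then
follows from $dA/dt = 0$, and the $E=0$ branch is closed-form. The
drug-free system yields the unstable extinction state `Eqm0` (eigenvalue
$+r$ along the tumor axis) and the stable capacity state `Eqm1`
$(K,0,0)$; under the default magnitudes the effector balance is negative
for every $A$, so no immune-controlled interior equilibrium exists — the
scan verifies this rather than assuming it. For treatment analysis,
`find_equilibria(params, C_const)` freezes the drug at a constant level
and reports the suppressed-tumor state `Eqm2`
($A^* = K(1 - \mu_{AC} C/(r(a+C)))$, existing while the kill rate stays
below $r$). This frozen-drug view deliberately stops short of Floquet
analysis of the periodically forced impulsive system: under real dosing
the drug decays between impulses, which is why a suppressed state that
looks locally stable at constant $C$ is not maintained once dosing stops.

## Calibration

`fit_muAC()` uses bisection, justified by the monotonicity of inhibition
in `mu_AC` (asserted on every `sweep_muAC()` call and property-tested),
run to 0.1 percentage points in inhibition *and* 0.5% relative bracket
width so that round-trip recovery of a generating `mu_AC` holds within 1%.
Only `mu_AC` is calibrated — deliberately mirroring the single-parameter
fit the experimental design supports; no joint fitting, no uncertainty
quantification beyond the recovery tests.

## The synthetic cohort generator

`generate_cohort()` stands in for the animal experiment: five groups
(control + four treated arms), four mice each, bled at treatment start and
Day 12, with the leukemic-cell count among $2\times10^5$ analyzed blood
cells recorded per bleed. The noise model has two layers chosen to mirror
how such data are actually produced:

* a per-mouse log-normal factor (default $\sigma = 0.2$, median 1) on the
  blood-sampling fraction, constant across that mouse's bleeds — real mice
  differ in blood volume and engraftment, and because the downstream
  estimator works on per-mouse frequency *changes*, this factor cancels,
  exactly as intended by the frequency-based experimental design;
* binomial sampling at the readout depth, since a cytometer counts a fixed
  number of events.

The sampling fraction (default 5e-7 per whole-body cell) maps tumor burden
to blood frequency; it is a nuisance constant — `estimate_inhibition()` is
provably invariant to it — set so frequencies stay in a realistic range
(2.5% at treatment start, ~37% for Day-12 controls). The generator does
*not* emulate RBC lysis efficiency, gating, doublets, spillover, drug
toxicity mortality, or inter-mouse growth-rate variation; passing tests
therefore demonstrate estimator/generator consistency and parameter
recovery under this idealized readout, not robustness to every real-data
artifact.

`estimate_inhibition()` implements the frequency-change estimator: each
mouse's frequency is normalized to the control-group mean at that
timepoint, per-mouse percent change is computed between bleeds, and the
treated group's mean change is differenced against the control group's. In
the noise-free limit this equals `inhibition_percent()` exactly (tested),
and at readout depth 2e7 the two agree to better than 0.01 pp.

Two-point growth estimation on logistic data is biased slightly low once
the control approaches capacity (the Day-0→Day-12 window gives ~0.0093/h
for a generating 0.01/h); the recovery test budgets 10% for this, and the
per-mouse dispersion diagnostic is returned alongside.

## Problem sizes

All simulations are desk-scale: 288–600 h spans at hourly output, single
trajectories in ~30 ms. The heaviest test (growth-rate recovery over 200
seeded cohorts) runs in ~10 s; the full suite in ~20 s; the acceptance
script in under a second.

## Known limitations

* The published per-arm inhibition figures are not reproduced under a
  single uniform convention (see above); quantitative comparisons against
  them carry that caveat.
* The immune compartment is effectively decorative at the default
  magnitudes; conclusions about immunotherapy cannot be drawn from it.
* No stochastic (birth–death) dynamics; extinction is asymptotic, never
  exact.
* Equilibrium analysis under dosing is frozen-drug only; no Floquet or
  bifurcation machinery.
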