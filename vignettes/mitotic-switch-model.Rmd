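---
title: "The two-switch model of mitotic control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-switch model of mitotic control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mitoswitch` implements a mass-action ODE model of the decision between
interphase and M phase in a mammalian cell. Two positive-feedback systems are
mutually antagonistic:

* **The Cdk1:CycB switch.** Cyclin-B-bound Cdk1 is inactivated by Wee1
  (phosphorylation of Cdk1-Y15) and reactivated by Cdc25. Cdk1 phosphorylates
  both regulators — inhibiting Wee1 and activating Cdc25 — closing two
  positive loops. Wee1 and Cdc25 each carry two phosphosites with identical
  per-site rate constants, so each regulator is a three-state chain
  (`Wee1`/`Wee1p`/`Wee1pp`, `Cdc25`/`Cdc25p`/`Cdc25pp`) with one conserved
  total (= 1 AU). The *unphosphorylated* Wee1 is the catalytically fast form;
  for Cdc25 the doubly phosphorylated form is fast.
* **The PP2A:B55 switch.** Greatwall kinase (Gwl), activated by Cdk1 (and by
  CycA:Cdk2), phosphorylates ENSA; phospho-ENSA stoichiometrically sequesters
  PP2A:B55 into an inactive complex from which the phosphatase slowly frees
  itself by dephosphorylating its inhibitor ("unfair competition"). PP2A:B55
  in turn dephosphorylates Gwl, Wee1, Cdc25 and the generic substrate. PP1
  both auto-activates *in trans* and is inhibited by Cdk1, and contributes to
  Gwl inactivation.

A generic Cdk1/PP2A:B55 substrate (`Subp`, total 1 AU) reports the global
phosphorylation state. The model has 10 dynamic concentrations, three
algebraic conservation relations (the pENSA:B55 complex, and the
singly-phosphorylated Wee1 and Cdc25 forms), and mass-action kinetics
throughout — the only explicit enzyme–substrate complex is pENSA:B55.

The ATP-analog Cdk1 inhibitor acts by rapid-equilibrium binding: every
Cdk1-driven rate carries the factor `1 / (1 + dose / Kd)` with `Kd = 0.025`
uM. The dose (`InhCdk1`) is a protocol input, not a model parameter, and
enters nowhere else.

### Units and parameters

Concentrations are in arbitrary units (AU) with most total pools normalised
to 1; exceptions are `B55Tot = 0.25` and the cell's total cyclin B
(`CycBTot`, median 8.18 AU in the population). Time is in minutes; doses and
`Kd` in uM (`Kd` is a binding constant, hence a concentration — the published
parameter table's `min^-1` annotation for it is a typographic slip, and the
package documents it as uM). Two reference parameterisations ship as flat
YAML files and as `mito_params(variant =)`: the high-precision set used to
draw the published bifurcation diagrams (canonical, `"xpp"`) and the rounded
descriptive table (`"table"`). Where the two disagree (e.g. `kiPP1` 0.0018
vs 0.002) the canonical set wins, because it is the executable source of the
published figures; the rounded set is preserved as an alternative.

## Protocols and classification

All protocols start from the printed interphase (G2-arrest) state. The 20-h
arrest itself is not simulated — the printed state *is* the arrested state;
`steady_state()` can refine it to the exact fixed point at 2 uM if wanted.

* **entry**: constant dose from `t = 0`; classify at 240 min.
* **exit**: dose 0 for 90 min (the cell enters mitosis), then the dose;
  classify 240 min later.
* **prophase**: dose 0 for `readd_time` (default 25 min), then the dose;
  relax to steady state and label by nearest stable attractor.

A cell is *mitotic* when `Subp/SubTot >= 0.30` (immunofluorescence-calibrated
boundary; inclusive at the boundary — the convention is arbitrary but fixed
and documented). Entry/exit use the state at the fixed endpoint time, matching
the fix-after-4-h endpoint assay; the prophase protocol uses attractor
identity because its claim is about a steady state. The schedule integrator
restarts exactly at each breakpoint so no step interpolates across the dose
discontinuity.

## Numerical choices

* **Integration**: `lsoda` (via deSolve) on a compiled right-hand side,
  `rtol = 1e-8`, `atol = 1e-10`. Output components in `(-1e-9, 0)` are
  clamped to 0 (mass-action positivity is exact; sub-tolerance drift is
  solver noise); larger violations raise. A pure-R right-hand side,
  written independently from the equations, and a compiled fixed-step RK4
  integrator serve as cross-checks in the tests.
* **Steady states**: chunked integration until the RHS max-norm falls below
  `1e-10` AU/min or 10,000 min pass; non-convergence is a flag, not an error.
* **Fixed points**: multi-start damped Newton (Latin-hypercube over the
  invariant box plus the two relaxed protocol endpoints), central-difference
  Jacobians (relative step `1e-7`), eigenvalue stability with threshold
  `Re < -1e-9`, duplicate roots merged at `1e-6` in pool-normalised max-norm.
  Brute-force seeded continuation replaces arclength continuation: the system
  is 10-dimensional and only fold locations and the stable branch structure
  are needed; unstable branches are reported only where the multi-start finds
  them.
* **Folds**: bisection on branch identity refined to `1e-4` uM; a monostable
  condition reports both folds absent (`NA`), never 0. When the entry- and
  exit-path estimates coincide within tolerance the system is monostable and
  both are reported absent.
* **Resolution defaults**: the intermediate (tristable) branch of the control
  model occupies a dose window only a few hundredths of a uM wide (~0.15 uM
  at median cyclin B, moving up-dose with cyclin B). The multistability
  census therefore defaults to a 41-point grid over [0, 2] uM and 64 Newton
  starts; a coarser scan can miss an existing branch.

## Population model and quadrature

Cell-to-cell variability enters *only* through total cyclin B, log-normal
with median 8.18 AU and arithmetic SD 4.31 AU on the natural scale (the
`sigma` of the underlying normal, 0.4518, is solved from the moment
identity). The default population evaluation is deterministic midpoint
quantile quadrature (64 equal-probability strata), which makes every reported
IC50 a reproducible float; Monte-Carlo sampling (`mode = "sample"`) is
provided for noise studies. Doubling the node count moves IC50s by under 2%
(tested).

Because a cell's endpoint classification is non-increasing in dose, the
per-cell curve is resolved by binary search over the dose grid; this is an
exact shortcut (identical to exhaustive per-dose simulation, asserted in the
tests), not an approximation. The synthetic-data generator similarly uses a
per-dose critical cyclin B found by bisection, then counts sampled cells
above it; equivalence with direct per-cell simulation is also tested.

The default dose grid is 25 log-spaced points in [0.01, 2] uM plus 0,
resolving both the tens-of-nM regime (Greatwall-depleted midpoints) and the
~0.5 uM regime (control exit); analyses of the Greatwall-depleted condition
add extra nodes below 0.2 uM.

## Synthetic data and fitting

`generate_dataset()` emulates the endpoint assay's statistical structure:
per condition x protocol x dose x biological repeat, `n_cells` (default 100)
cyclin B values are drawn from the log-normal, classified by the protocol,
and counted — 3 repeats by default. The noise model is purely binomial
sampling from the cyclin B distribution: no dose errors, no repeat-level
random effects, matching the assumption that cell-to-cell differences come
from cyclin B alone. One master seed; per-stratum streams are derived by a
fixed counter scheme so any subset regenerates identically.

The canonical fit is two-stage: stage 1 matches simulated to empirical 50%
levels across all condition/protocol groups with a homogeneous population
(the simulated IC50 is then the single-cell threshold dose of the candidate
median cell), determining the cyclin B median; stage 2 fixes the median and
fits the distribution SD by least squares on the full curves. Loss is squared
error on fractions, mirroring the original least-squares formulation; the
population heterogeneity — not counting noise — dominates the curves, so no
binomial likelihood is used by default. Rate-constant fitting ships as an
opt-in utility (seeded Latin-hypercube screen + `nlminb`, at most six free
constants) because the canonical pipeline only fits the cyclin B
distribution.

## What the synthetic data does and does not emulate

It reproduces: the log-normal cyclin B spread, the per-dose binomial counting
(N = 100 per repeat), the four perturbation conditions and both protocols.
It does not reproduce: photo-instability of the inhibitor under imaging,
dose-measurement error, repeat-level batch effects, partial penetrance of the
siRNA depletion, or any cell-cycle heterogeneity beyond cyclin B. Passing
recovery tests therefore show the estimator is consistent under the model's
own assumptions, not that real assay data are this clean.

## Known limitations and observed discrepancies

* With the canonical parameters, the double perturbation (Wee1 off, Gwl
  absent) reduces analytically to a monostable substrate balance whose 30%
  threshold falls at ~0.23 uM for the median cell; the simulated entry/exit
  midpoints (~230/240 nM) sit above the experimentally reported ~147/150 nM,
  although the qualitative signature — complete hysteresis collapse — is
  reproduced. The package reports what the model computes.
* The tristable window at median cyclin B lies near 0.15 uM; at 0.5 uM
  tristability requires cyclin B around 21–25 AU. Cells re-inhibited 25 min
  after release are already past the transition and are not captured; capture
  into the intermediate attractor does occur when the dose is re-added during
  the transition (e.g. 8 min for a 24-AU cell), which is the regime the tests
  demonstrate.
* No Hopf/oscillation analysis, no two-parameter bifurcation surfaces, no
  stochastic single-cell kinetics, no cyclin synthesis or degradation —
  protein totals are constant within a protocol by design.

## Problem sizes used by the shipped analyses

Population curves: 64 quantile nodes x 26 doses. Census: 41 doses x 64
Newton starts per condition. Prophase scan: 17-node quantile grid. Fitting
objective: 32 nodes. These defaults complete the full pipeline on one CPU in
a few minutes and are converged at the tested tolerances.
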