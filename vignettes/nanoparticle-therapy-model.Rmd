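---
title: "Modeling drug-loaded nanoparticle therapy in a multicellular tumor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-loaded nanoparticle therapy in a multicellular tumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoabm)
```

## The model

`nanoabm` simulates a 2D tumor of off-lattice cell agents coupled to a
diffusive microenvironment, treated with drug-loaded nanoparticles (NPs)
supplied from the domain boundary. The machinery is the hybrid
discrete-continuum architecture familiar from center-based multicellular
frameworks: substrates are continuum fields on a voxel grid, cells are
discrete agents, and each cell carries its own intracellular NP/drug
state.

### Substrates

Oxygen and extracellular NPs obey

$$\partial_t \rho = D \nabla^2 \rho - \lambda \rho
  - \sum_i U_i V_i\, \delta(x - x_i)\, \rho,$$

with Dirichlet conditions on all four domain edges representing a
vascularized far field. The solver is a dimension-split (locally
one-dimensional) backward-Euler scheme: tridiagonal solves along x then
y, then pointwise implicit decay, then re-pinning of boundary voxels.
It is unconditionally stable and first-order in time; the splitting is
the same compromise the established finite-volume solvers in this field
make. Cell uptake is applied after diffusion within each diffusion step,
implicitly per voxel, and each cell receives exactly its share
$U_i V_i \rho' \Delta t$ of the removed mass, so extracellular and
intracellular NP accounting match to rounding error.

Oxygen (D = $10^5\ \mu m^2$/min) relaxes to its quasi-steady profile
within a fraction of a minute, far below the phenotype time step, and its
uptake term is stiff. The engine therefore offers a quasi-steady oxygen
mode that relaxes the oxygen field with a fixed number of short
diffusion-uptake iterations per phenotype step rather than integrating
the fast transient on the whole diffusion clock. The default engine
configuration integrates oxygen faithfully at `dt_diffusion`; the
desk-scale experiment configurations enable the quasi-steady mode.

### Cells

Cells follow a Live cycle model: a viable cell divides at an
oxygen-modulated rate $b(\sigma) = \bar b\,
\min(1, \max((\sigma - \sigma_1)/(\sigma_2 - \sigma_1), 0))$ and
necroses at $r_{nec}(\sigma) = \bar r_{nec}\,
\min(1, \max((\sigma_3 - \sigma)/(\sigma_3 - \sigma_4), 0))$, with a
constant baseline apoptosis rate. Events are sampled per phenotype step
from independent exponential clocks ($P = 1 - e^{-r \Delta t}$) with
precedence necrosis > apoptosis > division when several fire at once;
the model paper gives rates, not a sampling scheme, so the scheme is a
package design choice and is validated against an event-driven
birth-death oracle in the test suite.

Mechanics are pairwise center-based forces: polynomial repulsion with
compact support on the summed radii and adhesion out to a multiple of
the summed radii, in an inertialess regime (velocity = net force /
drag). Volume uses a deliberately simplified model: daughters are born
at half the parent volume and relax exponentially back to the target
volume (default rate 0.0045/min, i.e. most of the regrowth within a few
hours); apoptotic cells shrink linearly over 8.6 h and are removed;
necrotic cells persist at frozen volume for 24 h, then lyse and are
removed. The full fluid/solid, nuclear/cytoplasmic volume regulation of
the source framework is intentionally out of scope.

### Nanoparticle pharmacokinetics

Internalization is saturable: a cell holding $n_I$ NPs takes up at
$dn_I/dt = r_I (1 - n_I/n^*) V_i \rho_{NP}$, and the matched tissue-level
sink uses $U_i = r_I (1 - n_I/n^*)$, so NP number is conserved between
field and cells exactly.

Internalized NPs age through $m$ discrete release states (default
$m = 10$; the figures of the source model show a multi-state spectrum
but print no value, so this is configurable). State $j$ carries load
fraction $f_j = 1 - j/m$, releases drug at $r_j = \gamma_1 f_j$, and
advances to the next state at $\alpha_j = m r_j / C^*$ (the time to shed
one state's worth of drug, $C^*/m$, at rate $r_j$). Released drug
accumulates in the cytoplasm, decays at $\lambda_{drug}$, and drives the
exposure accumulator $\mathrm{AUC} \mathrel{+}= (C/V_i)\,\Delta t$
(rectangle rule at the phenotype step, consistent with the forward-Euler
kinetics). Intracellular kinetics are advanced by forward Euler with
automatic sub-stepping so that (fastest rate x substep) stays below
0.005, which keeps trajectories within a fraction of a percent of the
matrix-exponential solution of the same linear system over kilominute
horizons.

Two deliberate options deserve note:

* **Final-state behavior.** Taken literally, the release equations let
  the final state release drug forever (it has no exit other than
  decay), so a cohort's cumulative release is unbounded over infinite
  horizons. The package implements this literal behavior by default and
  offers an `exhausted_removal` mode in which the final state empties at
  the same constitutive rate, capping per-NP release at $C^*$. Both are
  tested; neither is asserted as the "true" reading.
* **Immediate release** (`gamma1 = Inf`): arrivals deliver their full
  load $C^*$ to the drug pool on arrival and sit, spent, in the final
  state (counting toward saturation and subject to decay).

At division each daughter receives a fraction $x \in [0, 0.5]$ of every
release-state population -- inheritance is independent of release state
-- and the uninherited fraction $1 - 2x$ leaves the system (its fate is
not specified by the source model; removal keeps the ledger honest).
Released drug and AUC split 50/50 regardless of $x$, conserving drug
mass. Dying cells clear their NP compartment; every pathway
(internalized, decayed, cleared at death, lost at division, spent) is
tracked in a mass ledger that the engine can audit at output times.

### Pharmacodynamics

Effect follows a Hill response on the intracellular concentration
$c = C/V_i$ (or on AUC for exposure-driven drugs):
$E = E_{max} c^n / (EC_{50}^n + c^n)$. The targeted phenotype rate is a
linear interpolation $b = b_0 + (b_{max} - b_0) E / E_{max}$: cytostatic
drugs move the cycle-entry rate toward 0 (full arrest at maximal
effect), cytotoxic drugs move the apoptosis rate toward a configurable
multiple of baseline (default 6x; at full effect roughly one apoptosis
per two cell-days, comparable to the oxygen-limited birth rate, so kill
contends with proliferation without instant eradication).

### Dosing

Injections map to the NP field's time-varying Dirichlet boundary value:
each injection contributes dose x exp(-clearance x elapsed), doses
superpose, and systemic clearance is thereby modeled implicitly. The
default clearance half-life is 4 days, under which more than 87% of a
bolus has left the circulation by day 12. Total boundary exposure is
proportional to summed dose, so "one full dose" and "two half doses"
are exposure-matched comparisons.

## Parameters and defaults

Printed, verifiable quantities: NP vs oxygen diffusivity (6 vs
$10^5\ \mu m^2$/min), the swept internalization rates (0.0029 / 0.0058 /
0.0116 1/min), intracellular NP decay rates for 15/5/1-day half-lives
(3.2090e-5 / 9.6270e-5 / 4.8135e-4 1/min), extracellular decay for a
30-day half-life (1.6045e-5 1/min), and release-rate constants
$\gamma_1$ = 0.02, 0.1 umol/min plus immediate release.

Everything else lives in an unpublished supplementary table, so the
package's defaults are labeled assumptions, chosen once to land in the
regime the source model describes and then left alone:

| parameter | default | basis |
|---|---|---|
| $\bar b$ | 7.2e-4 1/min | framework-conventional Live-cycle rate (~1/day) |
| $\sigma_1, \sigma_2$ | 5, 38 mmHg | conventional hypoxia/physioxia thresholds |
| $\bar r_{nec}, \sigma_3, \sigma_4$ | 1/360 1/min, 5, 2.5 mmHg | framework-conventional |
| apoptosis base | 5.31667e-5 1/min | framework-conventional |
| cell volume | 2494 um^3 | framework-conventional |
| $n^*$ | 500 NPs | assumed saturation count |
| $C^*$ | 10 umol | assumed per-NP load; sets the drug unit scale |
| $\lambda_{drug}$ | ln2/480 1/min (8 h) | assumed; makes release speed matter |
| $EC_{50}$ | 0.03 umol/um^3 | assumed; half-effect at a moderately loaded cell |
| Hill n | 2 | conventional |
| reference dose | 0.01 NPs/um^3 | assumed boundary concentration of dose "C" |
| m | 10 | spectrum resolution; configurable |

## The desk-scale experiments

The full study ran tens of thousands of cells for 30 days with many
replicates on HPC. The package's experiment suite reproduces the
*orderings* of those findings at desk scale, not the absolute cell
counts: `scaled_tumor_config()` uses a 600 x 600 um domain (30 x 30
voxels), a 45-cell initial tumor, a 10-day horizon, and an oxygen
drawdown (cell uptake 30/min) under which untreated growth is
oxygen-limited at a few hundred cells. Because the horizon is
compressed threefold relative to the source study, the *delivery*
timescales compress with it while the cell clock stays physiological:
systemic clearance half-life 4/3 days (in place of 4), intracellular NP
decay 5/3 days (the compressed mid-range value; the release experiment
uses 5 days, the compressed analog of the slowest published 15-day
level), and the split-dose injection at day 5 mirrors the 0/15-day
split over a 30-day horizon. The saturation count is `n_star = 100` so
a unit dose engages the saturable-internalization nonlinearity. Time
steps are `dt_diffusion = dt_mechanics = 3` min and `dt_phenotype = 6`
min -- safe for the implicit field solver at this D and dx, and
resolving cell mechanics at the ~um/min velocity scale.

The four experiments (each 10 replicate seeds, reported as mean +/- 1
SD, seeds shared across arms so comparisons are paired) each state
their own conditions, as the full-scale study's figures do:

1. **Release rate** (cytostatic drug, slow intracellular NP decay).
   Slow release ($\gamma_1 = 0.02$) versus instantaneous release at
   matched dose. Sustained sub-saturating exposure contains cycling
   longer than a burst that decays at $\lambda_{drug}$ -- the
   containment-versus-aggressive-treatment behavior of adaptive-therapy
   theory.
2. **Extracellular decay** (cytotoxic drug, immediate release). Adding
   extracellular NP decay (10-day compressed half-life) versus none:
   NPs lost in transit never deliver drug, fewer kills compound into
   more viable cells at horizon.
3. **Schedule** (cytotoxic drug, doubled reference dose). Two half
   doses (days 0 and 5) versus one full dose at day 0, equal total
   dose: a single bolus overfills what cells can absorb before
   clearance and loads cells that die with their cargo, while the split
   schedule delivers into the partially regrown, capacity-free
   population.
4. **Inheritance** (cytotoxic drug, doubled reference dose). Viable
   cells at horizon as the inheritance fraction runs 0, 0.25, 0.5:
   treated-but-not-yet-apoptotic cells hand NPs to daughters, so
   therapy keeps acting across generations and the endpoint is
   non-increasing in $x$ (within replicate noise).

Mode assignments reflect where each mechanism is expressible: arrest
dynamics saturate quickly under a cytostatic drug (both schedule arms
would sit at full arrest for the whole horizon), so the dose-timing and
decay experiments use the cytotoxic drug, whose kill rate integrates
exposure over time; the release comparison is the classic containment
scenario and uses the cytostatic drug.

What desk scale does *not* show: absolute viable-cell counts comparable
to the source heatmaps, necrotic-core geometry of millimeter tumors, or
dose-response magnitudes -- the domain, horizon, and cell numbers are
two orders of magnitude smaller. Passing these tests demonstrates that
the implemented mechanisms interact in the directions the full-scale
study reports, not that the scaled system is quantitatively equivalent.

## What the synthetic scenarios emulate

All tests run on internally generated scenarios (`toy_tumor()`,
`single_cell_bath()`, `cohort_release()`, `scaled_tumor_config()`); no
external data exist anywhere in the pipeline. The bath fixture disables
diffusion and refreshes the field each step so the internalization ODE
has a closed form; the cohort fixture initializes the release cascade
for comparison against its matrix-exponential solution. These fixtures
are pure functions of (arguments, seed).

Real tumors differ in ways the generator does not emulate: 3D geometry,
vasculature and interstitial pressure, receptor-mediated uptake
heterogeneity, stromal and immune compartments, and drug release from
NPs still in transit (a named limitation of the source model, excluded
here too).

## Numerical choices and degenerate inputs

* Diffusion: first-order operator splitting; Dirichlet voxels are
  identity rows of the tridiagonal systems, so boundary flux is implicit
  in the solve. The shared interior-line factorization is precomputed
  per sweep.
* Cascade: forward Euler, auto sub-stepped (rate x h <= 0.005); a
  single-substep call enforces the stability guard
  `dt x max(alpha_j + lambda_NP) < 1` with an instructive error.
* Uptake: implicit per voxel; with several cells per voxel each gets its
  rate-proportional share, and the exchange is exactly conservative.
* Ties and degenerate inputs: coincident cell centers repel along a
  seeded random direction; `initial_radius = 0` yields one centered
  cell; `t_end = 0` returns the initial state; an empty region histogram
  is a 0-row matrix; `m = 1` is a single-state cascade with no
  transitions.
* Determinism: one RNG stream per run, consumed in a fixed order (event
  uniforms, then division directions, with rare mechanics tie-breaks);
  identical seeds give bit-identical trajectories.

## Known limitations

* 2D only, with a slab thickness to make volumes well-defined.
* The quasi-steady oxygen mode trades the fast oxygen transient for
  speed; it is inappropriate if oxygen dynamics on the minute scale are
  of interest.
* The literal release cascade is not drug-conserving over unbounded
  horizons (see above); use `exhausted_removal` when lifetime caps
  matter.
* Population-level NP counts are continuous rate-equation populations,
  not integer particles; stochastic single-NP effects (e.g. inheritance
  asymmetry between daughters) are outside scope.
* Mechanics use global pairwise interaction (O(n^2)); fine for the
  desk-scale population sizes the package targets.
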