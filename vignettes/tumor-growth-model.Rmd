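---
title: "An ATP-based multiscale model of avascular tumor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ATP-based multiscale model of avascular tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avasim)
```

## The model

`avasim` simulates the earliest, avascular phase of solid tumor growth
(up to roughly 1–2 mm, before angiogenesis), when the lesion is fed purely
by diffusion of nutrients from the surrounding vascularized tissue. It is a
hybrid, lattice-free multiscale model with three coupled layers:

1. **Tissue scale.** Five biochemical species — oxygen, glucose, metabolic
   waste, growth factors and growth inhibitors — evolve over a circular
   (or spherical) domain $\Omega$ by the reaction–diffusion equation
   $$\partial_t C_i - \nabla\cdot(D_i \nabla C_i) = Q_i,$$
   with Dirichlet values on $\partial\Omega$ (constant host-tissue supply)
   and cell-dependent source terms $Q_i$. Waste, growth factor and
   inhibitor have zero boundary values: whatever the cells produce is
   cleared by circulation at the domain edge.
2. **Cellular scale.** Off-lattice cells of 20 µm diameter carry a *health
   level* $h$: their ATP balance normalized by the quiescent maintenance
   production $H_Q$. Per iteration,
   $$\delta h = \frac{E_1 + E_2}{H_Q} - D\,\delta t,$$
   where $E_1$ and $E_2$ are the aerobic and anaerobic ATP production of
   the cell and $D = 1$/h is the normalized energy decay, fixed so a fully
   fed quiescent cell is in exact energy balance. Health drives state:
   above 1.5 a cell proliferates, below 0.5 it dies (irreversibly), and a
   proliferating cell becomes eligible for mitosis at the target
   $h \ge H_P/H_Q \approx 2.105$.
3. **Metabolism (the Warburg split).** A cell's realized oxygen and glucose
   uptake is split between complete oxidation — 6 O₂ per glucose, 30 ATP
   per glucose, capped by the available oxygen — and anaerobic glycolysis of
   the remaining glucose at 2 ATP per glucose. Fully supplied, a
   proliferating cell produces $H_P = 828$ and a quiescent cell
   $H_Q = 393.4$ mM/h/cm³ of ATP; the margin $H_P - H_Q = 434.6$ is the
   energetic cost of proliferation.

Mechanics follow the differential adhesion hypothesis: state-dependent
zero-rest-length springs ($k_{PP} > k_{PQ} > k_{QQ}$, necrotic cells
excluded) between separated neighbors, incompressible-body overlap
resolution by iterative pairwise projection, and chemotaxis of
proliferating cells along
$\vec m = \alpha\nabla C_O + \beta\nabla C_G - \gamma\nabla C_W$.
Motion is overdamped (first order in the force), the standard regime for
cell-scale mechanics in viscous tissue.

Stochastic mitosis uses the probability
$(h-1)\,M + \varepsilon$, $M = r(1+\mu)(1 + C_{GF} - C_{GI})$,
clamped to $[0,1]$, with a hard Hayflick cutoff at 60 generations; a mother
divides into two daughters at her position, each inheriting half her health.
A roaming cancer stem cell performs a reflected random walk and deposits one
fresh cancer cell every 70 iterations, seeding satellite tumors.

## Population reduction

Aggregate growth reduces to logistic dynamics
$dN/dt = rN(1 - N/K)$. The package fits sigmoid families (logistic,
Gompertz, Hill, Chapman, Boltzmann) to simulated series by
Levenberg–Marquardt least squares with analytic initialization (asymptote =
maximum count, midpoint at half-maximum, rate from the central slope), and
realizes the stochastic counterpart as a Gillespie pure birth process with
hazard $h(N) = rN(1-N/K)$ and exponential waiting times. The literature this
model derives from prints the waiting-time rule as $\delta t = e^{h}$; that
form is not a probability distribution, and since the construction is
explicitly Gillespie's, exponential sampling
($\delta t = -\ln u / h$) is the default. The printed map is retained
behind `printed_form = TRUE` for comparison.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $D_i$ | 0.0594 / 0.00152 / 0.002124 / 1e-6 / 1e-6 | cm²/h | diffusion constants (O₂, glucose, waste, GF, GI) |
| boundary $C_O$, $C_G$ | 0.00053, 0.005 | model-mM | host-tissue Dirichlet supply |
| uptake rates | 108/162 (P), 50/80 (Q) | mM/h/cm³ | per-state maximum O₂/glucose demand |
| $H_P$, $H_Q$ | 828, 393.4 | mM/h/cm³ | full ATP production per state |
| thresholds | 1.5 / 0.5 / $H_P/H_Q$ | — | proliferation / necrosis / mitosis target |
| $r$ | 0.0315 | /iteration | base mitosis probability |
| $\sigma$ | 0.01 | — | mitosis noise SD (unstated upstream; small so noise perturbs, not dominates) |
| Hayflick limit | 60 | generations | division ceiling |
| stem period | 70 | iterations | stem-cell spawn interval |
| dissolution delay | 100 | iterations | necrotic persistence (unstated upstream) |
| `uptake_coupling` | 2e-5 | — | dimensionless uptake efficiency (see below) |
| $k_{PP}, k_{PQ}, k_{QQ}$ | 1, 0.5, 0.25 | model | adhesion stiffness (given only by order of magnitude) |
| $\alpha,\beta,\gamma$ | 1, 1, 0.5 | model | chemotaxis weights (unstated upstream) |
| mobility | 0.1 | cm/force/h | overdamped mobility |
| $dt$ | 1 | h | one iteration (the metabolic rates are per hour) |

**Units.** The source literature mixes mM, mM/cm³ and mmol/L; all
concentrations here live on a single face-value scale ("model-mM") on which
every printed constant is stored as printed. The hemoglobin conversion
g/L ÷ g/mol is kept at its printed face value (0.0019–0.0023 for
122–150 g/L), which is consistent with the 0.002 large-vessel constant the
derivation chain uses.

**The uptake coupling.** The per-cell-volume metabolic rates (~10²
mM/h/cm³) and the field boundary concentrations (~10⁻³ model-mM) differ by
five orders of magnitude, and the source model never states how the two
couple. We treat table rates as *maximum demand*, scaled by local
availability relative to the boundary (host-supply) concentration. The
engine realizes this through a competitive uptake step
(`nutrient_uptake()`): each cell's demand contributes to a nodal uptake
intensity λ (scaled by the cell-footprint-to-node-volume ratio, so the
coupling is independent of grid resolution, and by one dimensionless
efficiency, `uptake_coupling`); over a step the node concentration decays
as C·e^(−λ·dt) and each cell draws from the time-averaged concentration.
This is exact for static cells, unconditionally stable, and never
overdraws a node — explicit linear deposition at dt = 1 h alternates
between total starvation and full supply whenever λ·dt approaches 1, which
destabilizes the population dynamics. The default efficiency (2e-5) was
chosen once so an isolated cell realizes nearly its full glucose demand
(oxygen, whose boundary concentration is ~10× lower, is partially limited,
and the anaerobic pathway compensates — the energy balance of a lone cell
stays far above the quiescent maintenance level) while touching-density
packings sit at the quiescence margin, so tumors of order 10³ cells
deplete their core below the quiescence and necrosis thresholds — the
regime in which the characteristic layered morphology emerges. Production
species scale with the cell's realized metabolic activity (ATP as a
fraction of the state's full production) rather than with an availability
fraction, which is undefined for species whose boundary value is zero;
necrotic inhibitor release is unscaled, as it reflects decay rather than
metabolism.

**The Hill boundary constant.** The oxygen boundary value 0.00053 is taken
from the printed plasma-oxygen solution of the Hill saturation relation.
The printed solution pair does not actually satisfy the printed relation
under the printed constants (recorded as unresolved); we implement the
relation verbatim, ship 0.00053 as the default boundary constant on the
authority of the text, and provide `invert_hill()` for users who want a
self-consistent pair.

## Numerical choices

- **Finite differences, not finite elements.** Concentrations are described
  upstream as computed "by finite element methodology" with no mesh,
  elements or solver given. On a regular grid with a circular Dirichlet
  mask, second-order central differences are equivalent at the accuracy
  this model needs and far easier to verify; the results depend on
  diffusion qualitatively, not on the discretization family.
- **Backward Euler by default.** The oxygen diffusion length per one-hour
  iteration (~0.5 cm) exceeds the domain, so explicit stepping would need
  ~10⁴ subcycles; the implicit operator is assembled and
  Cholesky-factorized once per species and reused every iteration. The
  explicit scheme (with automatic sub-cycling and a stability refusal when
  sub-cycling is disabled) is kept for verification, where its conservation
  structure is easy to audit.
- **Clamping.** Explicit sinks can overdraw a nearly empty node; negative
  concentrations are clamped to zero and the clamped mass is accumulated on
  the field for audit.
- **Deposition.** A cell's source total is spread over the surrounding grid
  nodes by cloud-in-cell (multilinear) weights, renormalized onto interior
  nodes, so each cell's total rate is conserved exactly and Dirichlet nodes
  receive nothing.
- **Overlap resolution** iterates pairwise half-overlap projections until
  the maximum overlap is below 1% of the radius or a sweep cap is reached
  (logged, state remains valid). Coincident centers (fresh daughters)
  separate along a random direction from the seeded stream. Plain
  projection (`relax = 1`) is the default because it is exact for an
  isolated pair; over-relaxation is available for dense packings.
- **Adhesion acts on separated neighbors only.** A zero-rest-length spring
  applied to an overlapping pair would oppose the incompressibility
  projection; contact and overlap are owned by the projection step, the
  spring by the separated regime up to 1.2× the summed radii.
- **Operator order** within an iteration: sources → diffusion → health →
  classification → mitosis → stem cell → dissolution → mechanics. Mechanics
  run last so daughters separate in the iteration they appear.
- **Chemotaxis saturation.** The raw gradient vector is scaled through
  `tanh` against a boundary-scale reference gradient so that one iteration
  moves a cell at most one radius — preventing unphysical jumps across the
  domain in the steep early gradients.
- **Ties and degenerate inputs.** Coincident mechanics pairs contribute no
  spring force (logged); constant population series are rejected as
  degenerate by the sigmoid fitter with an initialization report;
  region reports tolerate absent annuli (NA radii).

## What the synthetic generators emulate

`generate_fixture()` builds known-truth snapshots for the morphology
analysis: `layered_tumor` (pure necrotic core, quiescent annulus,
proliferating rim at prescribed radii — the idealized end state),
`planted_clusters` (necrotic agglomerations in a quiescent sea — the mixed
annulus's hallmark), `random_gas`, and `two_tumors` (a stem-cell satellite
scenario). They are lattice packings with exact region membership, so
recovery tests have unambiguous ground truth. They do **not** emulate
mechanical jitter, partial-volume mixing at region borders, or the ragged
interfaces of real simulated tumors; passing them shows the analysis
recovers geometry, not that a simulation reproduces histology.

The engine's own study conditions are scaled to a desk: 2-D, 100×100
nodes at 0.002 cm spacing (one node per cell diameter), with the circular
biological domain set to radius 0.05 cm so the population reaches its
nutrient-capped plateau within 300 hourly iterations; populations of order
10³, about two to three minutes on one CPU. The reference populations this
model's literature reports (~10⁷ cells, from an unpublished domain
configuration) are out of scope; the printed fitted constants serve as
generator parameters for recovery tests instead of as simulation targets.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1L)   # 100x100 grid, 300 iterations
run <- run_simulation(cfg)
print(run)
plot(run, "population")

# morphology of the final snapshot
classify_regions(run$cells)
find_agglomerations(run$cells)
find_tumor_islands(run$cells)

# macroscopic reduction of the quiescent curve
fit <- fit_sigmoid(run$series$quiescent, run$series$iteration)
print(fit)
```

## Known limitations

- At desk scale the plateau-phase tumor is strongly intermixed: dissolution
  churn and division pressure interleave necrotic and living cells, so the
  radial region report often finds broad mixed annuli rather than the pure
  core/annulus/rim sequence of the idealized picture (which the analysis
  recovers exactly on layered fixtures). Larger, slower runs segregate
  more cleanly.
- Quiescent cells can never re-enter proliferation under the per-state
  demand caps (their maximum ATP production exactly balances decay); growth
  is carried entirely by the proliferating rim. This is a direct
  consequence of the model's energy bookkeeping, not an implementation
  choice.
- The two signaling species ("%/h/cm³") are treated as ordinary
  concentration rates; their absolute scale is only meaningful relative to
  the mitosis modulation term.
- No cell-cycle phases, no ECM degradation or invasion, no angiogenesis,
  no 3-D rigid-body rotation; 3-D runs are supported but default
  resolutions are tuned for 2-D.
- The energy decay rate $D(t)$ is constant; the defining sentence fixes it
  to the quiescent production rate, and nothing upstream varies it in time.
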