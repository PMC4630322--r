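# avasim

Multiscale, lattice-free simulation of avascular tumor growth in R.

`avasim` is for computational-oncology researchers who want a transparent,
fully scriptable model of the earliest phase of solid tumor growth — the
stage (≤1–2 mm) in which a lesion is fed purely by diffusion from the
surrounding vasculature. The model couples:

- **Reaction–diffusion fields** for five biochemical species (oxygen,
  glucose, metabolic waste, growth factors, growth inhibitors) over a
  circular domain Ω with Dirichlet boundaries:
  ∂C_i/∂t − ∇·(D_i∇C_i) = Q_i, with per-cell source/sink terms Q_i.
- **An ATP-denominated health function** per cell. Realized oxygen/glucose
  uptake is metabolized through the Warburg split — 6 O₂ + 1 glucose → 30 ATP
  aerobically, remaining glucose → 2 ATP anaerobically — and the health level
  advances by δh = (E₁+E₂)/H_Q − D·δt. Health drives quiescence (≈1),
  proliferation (>1.5), necrosis (<0.5, irreversible) and mitosis
  (h ≥ H_P/H_Q ≈ 2.105).
- **Off-lattice cell mechanics**: differential-adhesion springs
  (k_PP > k_PQ > k_QQ, necrotic pairs excluded), incompressible overlap
  resolution, chemotaxis m = α∇C_O + β∇C_G − γ∇C_W for proliferating cells.
- **Stochastic mitosis** with probability (h−1)·M + ε,
  M = r(1+μ)(1+C_GF−C_GI), a Hayflick limit of 60 generations, and a roaming
  cancer stem cell that seeds a new cancer cell every 70 iterations.
- **A population reduction**: logistic growth dN/dt = rN(1−N/K), sigmoid
  fitting (logistic/Gompertz/Hill/Chapman/Boltzmann) of simulated series,
  and a Gillespie pure birth process with hazard h(N) = rN(1−N/K).
- **Morphology analysis** of the emergent radial structure: necrotic core
  Ω_N, mixed necrotic–quiescent annulus Ω_A with satellite agglomerations,
  pure quiescent annulus Ω_Q, proliferating rim, and the boundary radii
  U_N ≤ U_Q1 ≤ U_Q2 ≤ U_T.

See the vignette (`vignettes/tumor-growth-model.Rmd`) for the full model
description, parameter table and numerical choices.

## Worked example

```r
library(avasim)

# recompute the model's reference constants
head(validate_constants(), 3)
#>                    quantity computed reference pass
#> 1 proliferating aerobic ATP      540       540 TRUE
#> 2   proliferating total ATP      828       828 TRUE
#> 3     quiescent aerobic ATP      250       250 TRUE

# the default desk-scale simulation: 100x100 nodes (0.002 cm spacing),
# circular domain of radius 0.05 cm, 300 hourly iterations
run <- run_simulation(simulation_config(seed = 1L))
print(run)
#> Tumor simulation run: 300 iterations, 7729 cells at end
#>   final counts: proliferating 1095, quiescent 144, necrotic 6490
#>   first quiescent cell at iteration 37; first necrotic at 40
plot(run, "population")      # P/Q/N counts over time
plot(run, "snapshot")        # final cell configuration

classify_regions(run$cells)  # radial region report (U_N, U_Q1, U_Q2, U_T)
find_agglomerations(run$cells)  # necrotic agglomerations outside the core
find_tumor_islands(run$cells)   # separate living tumors (stem-cell satellites)

# macroscopic reduction: the living-cell curve is best fit by a logistic
living <- run$series$proliferating + run$series$quiescent
fit_sigmoid(living, run$series$iteration)
#> logistic sigmoid fit (R-squared = 0.990259)
#>           A           k          t0
#> 1.19000e+03 7.49236e-02 1.14439e+02
compare_sigmoid_models(living, run$series$iteration,
                       c("logistic", "gompertz", "hill"))
#>     family r_squared n_par converged
#> 1 logistic 0.9902586     3      TRUE
#> 2     hill 0.9863195     3      TRUE
#> 3 gompertz 0.9827545     3      TRUE

# stochastic logistic birth process vs the closed form
tr <- simulate_birth_process(K = 1000, r = 0.2)
```

The run starts from one founder cell at the domain center, grows
exponentially while the environment is rich (first ~35 iterations),
develops quiescent cells as local nutrients deplete (iteration 37 above),
then necrosis (iteration 40), and plateaus around 1,200 living cells — the
population the boundary nutrient inflow can sustain; with the stem cell
enabled, satellite tumors appear.

A command-line interface wrapping these functions ships at
`inst/cli/avasim.R` with subcommands `run`, `analyze`, `fit`, `hazard`,
`fixture` and `validate`.

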