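# poresim

Voxel-graph simulation of microbial decomposition of organic matter in the
water-saturated pore space of soil.

Soil microbial habitats live inside a tortuous pore network that micro-CT
imaging resolves as a binary 3D image (pore = 0, solid = 1). poresim is for
soil scientists and modelers who want to simulate carbon turnover directly
on that image — no meshing, no geometric simplification — and for users of
coarse pore-network (ball) models who want to calibrate their diffusional
conductances against voxel-scale simulations instead of external reference
solvers.

## The model

**Transport.** The pore voxels form a graph `G(V, E)` under strict
6-connectivity. With voxel volumes normalized, Fick's law along the edges
gives the graph diffusion equation for the dissolved-organic-matter (DOM)
mass vector `M(t)`:

    dM/dt = -D · Δ · M

where `Δ` is the graph Laplacian (degrees on the diagonal, −1 per edge).
Rows of `Δ` sum to zero, so the closed-system boundary and exact mass
conservation are built in. Forward-Euler stepping is stable for
`dt ≤ 1/(D·deg_max)`; backward Euler (solved matrix-free by a
Jacobi-preconditioned conjugate gradient) is unconditionally stable and
tolerates ~100× larger steps at matching layer profiles.

**Reaction.** Each voxel carries five carbon pools — microbial biomass MB,
DOM, soil and fresh organic matter SOM/FOM, and respired CO₂ — coupled by
Monod growth `v_DOM·DOM/(K_DOM+DOM)·MB`, first-order mortality (fraction
`β` recycled to DOM, `1−β` to SOM), respiration `ρ·MB`, and hydrolysis
`v_SOM·SOM + v_FOM·FOM → DOM`. Defaults are the *Arthrobacter* sp. 9R set
(`ρ=0.2, μ=0.5, β=0.55, v_SOM=0.01, v_FOM=0.3, v_DOM=9.6, K_DOM=0.001`,
rates per day). Diffusion and transformation are coupled by operator
splitting with sub-stepping.

**Pore-network improvement.** A coarse model of overlapping balls exchanges
mass with flux `F_ij = -Dc·dt·θ_ij·(m_i/v_i − m_j/v_j)`. The per-edge
conductances `θ_ij` — classically the geometric `S_ij/d_ij` (contact
surface over center distance) — are *learned* by normalized stochastic
gradient descent on pairs of ball-mass distributions generated by the
voxel-scale solver, using an explicit or implicit one-step objective
(update: `θ ← θ − lr · ∇L/‖∇L‖`, learning rate halved on a fixed
schedule).

## Worked example

```r
library(poresim)

# a connected synthetic pore geometry (stand-in for a segmented micro-CT)
pk <- generate_ball_packing(dims = 32, n_balls = 12,
                            radius_range = c(4, 7), seed = 320)
g <- build_voxel_graph(pk$image)
g
#> voxel_graph: 3088 pore voxels, 8418 edges (6-connectivity), image 32 x 32 x 32

# 289.5 ug DOM spread over the pore space; 1000 bacterial spots totalling
# 5.2e7 cells x 5.41e-8 ug C = 2.8132 ug C
state0 <- initialize_scenario(g, dom_total = 289.5,
                              dom_placement = "uniform", n_spots = 1000,
                              cells = 5.2e7, mass_per_cell = 5.41e-8,
                              seed = 9)
round(100 * compound_fractions(state0), 4)
#>      mb     dom     som     fom     co2
#>  0.9624 99.0376  0.0000  0.0000  0.0000

# two simulated days, implicit diffusion at 300 s steps, asynchronous kinetics
rec <- run_coupled(state0, g, bio_params(), D = 100950,
                   dt_diffusion = 300, dt_transformation = 300,
                   duration = 2 * 86400, cadence = 43200)
round(rec$totals, 3)
#>           mb     dom    som fom    co2
#> [1,]   2.813 289.500  0.000   0  0.000
#> [2,] 209.016  72.904  5.504   0  4.889
#> [3,] 227.902   0.679 33.718   0 30.014
#> [4,] 184.559   0.553 56.643   0 50.559
#> [5,] 149.590   0.452 75.069   0 67.203
rec$drift
#> [1] 5.83382e-16
```

Reading the output: biomass blooms on the available DOM (rows 1–3), then
starves and declines while mortality recycles carbon into SOM and
respiration accumulates CO₂; each row sums to the initial 292.31 µg of
carbon to machine precision (`drift` is the relative conservation error
over the whole run).

Conductance learning, in brief:

```r
net  <- build_ball_network(pk$balls)          # theta initialized to S/d
dat  <- generate_training_data(net, image = pk$image, n_scenarios = 6,
                               sim_dt = 0.1, record_interval = 10,
                               duration = 500, seed = 11)
fit  <- sgd_train(dat, net, training_config(epochs = 1000, lr = 0.5,
                                            lr_halve_every = 50))
fit$theta                                     # learned conductances
```

A command-line surface (`gen-synth`, `build-graph`, `diffuse`, `simulate`,
`voxelize-balls`, `train-conductance`, `profile`) lives at
`inst/cli/poresim.R`; each run writes a YAML manifest next to its outputs.

## Package layout

- `R/` — voxel graph and Laplacian, diffusion schemes and PCG, five-pool
  kinetics, operator-split coupled simulator, ball networks, conductance
  learning, synthetic geometries, I/O (TIFF/raw volumes, CSV, YAML).
- `vignettes/poresim-methods.Rmd` — the model, numerical choices, and
  limitations, in detail.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (brute-force scans, dense matrix exponentials,
  closed forms, finite differences).
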