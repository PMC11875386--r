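---
title: "Methods: voxel-graph diffusion, five-pool kinetics, and conductance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-graph diffusion, five-pool kinetics, and conductance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poresim)
```

poresim simulates the microbial decomposition of organic matter in the
water-saturated pore space of soil, at the voxel resolution of binary 3D
computed-tomography images. This vignette is the package's account of the
model, its numerical treatment, the choices that were genuinely open, and
what the synthetic test geometries do and do not demonstrate.

## The pore space as a graph of voxels

A binary image tags pore voxels 0 and solid voxels 1. Under full saturation
the pore space is water-filled, so the system has two phases (solid/liquid)
and diffusion is the only transport mechanism. `build_voxel_graph()` turns
the pore voxels into graph nodes connected by strict 6-connectivity (face
adjacency); 18- or 26-connectivity is deliberately not offered. Nodes are
numbered in raster order (x fastest, then y, then z), which fixes every
downstream vector ordering and makes runs bit-reproducible. Voxel indices
are 0-based everywhere, so "the first two z layers" always means
`z %in% c(0, 1)`.

Boundary conditions need no machinery: a voxel on the image boundary simply
has fewer neighbours, which is exactly the zero-flux (closed-system)
boundary. Consequently total mass — and, with the transformation model,
total carbon — is a conserved quantity of the continuous model, and the
package treats conservation as a hard invariant to be tested rather than a
diagnostic to be watched.

## Diffusion: the graph diffusion equation

Dissolved organic matter (DOM) is the only diffusing compound. With voxel
volumes normalized, mass and concentration coincide, and Fick's first law
applied along each edge gives the graph diffusion equation

$$\frac{dM}{dt} = -D\,\Delta M,$$

where $\Delta$ is the graph Laplacian (`laplacian()`): node degrees on the
diagonal, $-1$ per edge, rows summing to zero. Two time discretizations are
provided:

* **explicit** (forward Euler), `explicit_step()`:
  $M^{k+1} = M^k - D\,\delta t\,\Delta M^k$;
* **implicit** (backward Euler), `implicit_step()`:
  $(I + D\,\delta t\,\Delta) M^{k+1} = M^k$.

The explicit update is a convex combination of neighbour values whenever
$D\,\delta t\,\deg_{\max} \le 1$; `stable_timestep()` exposes this
sufficient bound $1/(D \deg_{\max})$ rather than any dataset-specific
constant. Above the bound, a negative mass is a hard error — clipping would
silently destroy conservation.

The implicit system matrix is sparse, symmetric positive definite, and is
solved matrix-free by a conjugate gradient with the Jacobi preconditioner
$t_{ii} = 1/b_{ii}$ (`pcg_solve()`), relative-residual tolerance `1e-10`
and iteration cap `max(1000, n)` by default. The tight default keeps
conservation intact over long runs. Because an iterative solve leaves a
residual mass defect of the order of the tolerance, each implicit step
redistributes that defect uniformly over the nodes; the correction is
bounded by the solver tolerance and restores conservation to floating
precision per step. (It is applied globally, so over a run it can move mass
of order `1e-10` relative between disconnected components; the
per-component conservation tests bound exactly this.)

**Units.** The diffusion coefficient is configured in voxel² day⁻¹
(default `100950`, an aqueous small-organic-molecule diffusivity expressed
at a 24 µm voxel edge) while time steps are in seconds; the single
conversion factor 1/86400 lives in `per_second()`/`per_day()` and is
tested. Physical voxel size enters nowhere else — resolution only rescales
the parameters.

## Transformation: five carbon pools with Monod kinetics

Each node carries five carbon masses: microbial biomass (MB), dissolved
(DOM), soil (SOM) and fresh (FOM) organic matter, and respired CO₂. The
kinetics, per node,

$$
\begin{aligned}
\dot x^{\mathrm{MB}} &= \frac{v_{\mathrm{DOM}}\,x^{\mathrm{DOM}}}{K_{\mathrm{DOM}} + x^{\mathrm{DOM}}}\,x^{\mathrm{MB}} - (\rho + \mu)\,x^{\mathrm{MB}},\\
\dot x^{\mathrm{DOM}} &= -\frac{v_{\mathrm{DOM}}\,x^{\mathrm{DOM}}}{K_{\mathrm{DOM}} + x^{\mathrm{DOM}}}\,x^{\mathrm{MB}} + \beta\mu\,x^{\mathrm{MB}} + v_{\mathrm{SOM}} x^{\mathrm{SOM}} + v_{\mathrm{FOM}} x^{\mathrm{FOM}},\\
\dot x^{\mathrm{SOM}} &= (1-\beta)\mu\,x^{\mathrm{MB}} - v_{\mathrm{SOM}} x^{\mathrm{SOM}},\qquad
\dot x^{\mathrm{FOM}} = -v_{\mathrm{FOM}} x^{\mathrm{FOM}},\qquad
\dot x^{\mathrm{CO_2}} = \rho\,x^{\mathrm{MB}},
\end{aligned}
$$

move carbon only between pools of the same node, so the rates sum to zero
and each step conserves carbon exactly in the algebra. The default
parameters are the *Arthrobacter* sp. 9R set (rates day⁻¹): respiration
ρ = 0.2, mortality µ = 0.5, recycling fraction β = 0.55 (dead biomass split
β to DOM, 1−β to SOM), hydrolysis v_SOM = 0.01, v_FOM = 0.3, Monod growth
v_DOM = 9.6 with half-saturation K_DOM = 0.001 in the state's mass unit.
Because the respiration rate was calibrated on growth/respiration curves,
it lumps maintenance and growth respiration.

`transform_step()` discretizes the system with explicit Euler in two modes:

* **synchronous** — all pools update from the time-*t* values;
* **asynchronous** — the processes are applied as sweeps in the fixed order
  *growth → mortality → respiration → hydrolysis*, each reading the state
  the previous sweep left. The order is a single documented constant. The
  design question of interleaving per node versus per process was resolved
  in favour of process sweeps across all nodes: it is vectorizable and
  node-order independent.

The two modes differ by $O(\delta t^2)$ (tested by a Richardson-style
sweep). Monod uptake is capped at the DOM actually present so a finite step
cannot overdraw a voxel; this cap is the only guard, and any other pool
driven negative by a too-large step raises an error naming the node and
pool. For the default rates, $\delta t \le 1/(\rho + \mu + v_{\mathrm{DOM}})
\approx 0.097$ day keeps MB nonnegative; the coupled-simulation defaults
(seconds-scale steps) are far below every such bound.

## Coupling by operator splitting

`run_coupled()` alternates transformation and diffusion. Within a macro
step of length `max(dt_diffusion, dt_transformation)` the process with the
smaller step is sub-stepped so both advance the same elapsed time; both
steps must divide the macro step, which must divide the output cadence.
Transformation runs first by default (the splitting order is a
configuration option for sensitivity checks, and flips the $O(\delta t)$
splitting error, not the conserved totals). Bacterial "spots" are
initialized as point masses at distinct pore voxels sampled without
replacement under a seed; a spot's spatial extent is a single voxel, the
smallest representable cluster.

One scenario detail is scale invariance: all terms of the kinetics except
Monod uptake are linear, so total-mass units are arbitrary up to the pair
$(K_{\mathrm{DOM}},$ mass unit$)$; configured totals are treated as
abstract carbon mass in µg.

## Ball networks and their conductances

The coarse pore-network model represents the pore space by overlapping
balls. Two balls are adjacent iff they strictly overlap (tangency gives
zero contact and is excluded); each edge carries the contact surface
$S_{ij}$, the center distance $d_{ij}$ and a diffusional conductance
$\theta_{ij}$, and the flux is

$$F_{ij} = -D_c\,\delta t\,\theta_{ij}\left(\frac{m_i}{v_i} - \frac{m_j}{v_j}\right).$$

Explicit and implicit steps mirror the voxel schemes; the implicit system
is SPD in concentration variables for $\theta \ge 0$ and is solved by the
same preconditioned conjugate gradient.

Open representation choices, and how they were fixed:

* $S_{ij}$ defaults to the area of the sphere–sphere intersection disc
  (standard lens geometry); when one ball contains the other there is no
  intersection circle and the great disc of the contained ball is used.
  A voxel-counted alternative (shared faces between the two balls'
  partition cells) is available via `surface = "voxel"`.
* Ball volume $v_i$ is the analytic $\tfrac43\pi r^3$; the partition-cell
  voxel count is available from `map_voxels_to_balls()` for diagnostics.
  Overlap makes the two differ; the analytic choice keeps $v_i$ independent
  of the voxelization resolution.
* The classical initialization is $\theta_{ij} = S_{ij}/d_{ij}$, optionally
  scaled by a global calibration factor `alpha` (the legacy calibrated
  value 0.6 is supported as an input; fitting it against an external
  reference solver is out of scope).
* Voxels inside several balls are assigned to the nearest center, ties to
  the lowest ball index — a deterministic partition, required for exact
  round-tripping between ball masses and voxel masses.

## Learning the conductances from voxel-scale data

`generate_training_data()` runs seeded explicit voxel-graph diffusion
scenarios on the voxelized ball image (random total mass, random per-voxel
shares), records the state every `record_interval` seconds, and aggregates
to ball masses, yielding pairs $(X_p, Y_p)$ one interval apart. Two
objectives are offered over a batch of pairs (`loss_l1()`, `loss_l2()`):
the mean squared residual of the explicit one-step prediction against
$Y_p$, and the mean squared residual of $X_p$ against the implicit-scheme
left-hand side applied to $Y_p$. The implicit objective is the default.
Both are quadratic in $\theta$; their exact gradients carry both endpoint
terms of each symmetric edge parameter and are verified against central
finite differences to better than $10^{-5}$ relative.

`sgd_train()` implements normalized stochastic gradient descent: per epoch
(one batch update, not a data pass) a batch is sampled, the gradient is
normalized, and a step of length equal to the current learning rate is
taken, followed by projection onto $\theta \ge 0$ (a negative conductance
breaks the SPD structure and conservation). Normalizing *per coordinate*
would degenerate to sign descent, so the default divides the whole gradient
vector by its Euclidean norm; sign mode remains available behind
`normalization = "sign"`. The tracked loss is evaluated on a fixed probe
batch of four pairs chosen by the seed at the start. Stopping is a fixed
epoch budget, plus an optional plateau stop (probe-loss change below
`1e-12` over 50 epochs).

The default schedule is learning rate 0.1 halved every 10 epochs for 1000
epochs with batches of four. Note a property of normalized updates: the
total distance the parameters can travel is the sum of the learning rates
(here $0.1 \times 10 \times 2 = 2$). The desk-scale fixtures in this
package have conductance vectors of norm ≈ 80, so their experiments use a
schedule with the same constant-then-halving shape but a larger travel
budget (`lr = 0.5` halved every 50 epochs, budget 50), chosen once from the
fixture's own scale — the budget must cover the plausible correction
$\|\theta^* - S/d\|$. The probe loss, not the schedule, is the measure of
success.

## Numerical choices and validation design

* **Tolerances.** PCG relative residual `1e-10` (tests that compare against
  dense solves tighten it to `1e-13`); conservation asserted at `1e-10`
  per step and `1e-9` over five simulated days; carbon conservation of the
  kinetics at `1e-12`.
* **Spectral validation.** The `L x 1 x 1` chain image realizes the path
  graph, whose Laplacian eigenvalues $2 - 2\cos(k\pi/L)$ are known in
  closed form. The implicit solver is checked against the eigen-expansion
  to $10^{-6}$ using the fundamental mode as the initial profile and
  $\delta t = 10^{-4}$: the backward-Euler error on mode $k$ is
  $O(\lambda_k^2 \delta t)$, so the fundamental mode isolates the
  time-discretization error at exactly the tolerance being claimed, while
  rough initial data is covered separately by the first-order convergence
  tests against the dense matrix exponential.
* **Scheme agreement.** Explicit stepping at half the stability bound and
  implicit stepping at twenty times the bound are compared through layer
  profiles on a fixed 16³ packing over a horizon of 30 coarse steps —
  enough steps that the comparison probes the schemes, not a single-step
  truncation error — and must reach intercorrelation (cosine) ≥ 0.999.
* **Learning evaluation horizon.** The layer-profile comparison between the
  voxel solution and the ball network runs for 60 s on the 48³ fixture:
  diffusion times scale as $L^2$, so this corresponds to the classical
  ~1.7 h comparison horizon on a 512-wide image. The learned conductances
  are evaluated in the implicit scheme at the 10 s interval they were
  trained on.
* **Problem sizes.** The test-suite and the acceptance script run on 16³,
  32³ and 48³ synthetic packings (hundreds to ~11 000 pore voxels,
  20 balls), a five-day coupled run at 300 s steps, and 200–300 training
  pairs — sizes chosen so every check also has a dense or closed-form
  oracle within reach.
* **Degenerate inputs.** All-solid images give a valid empty graph; an
  empty graph has no stable time step; zero-norm profiles have no
  intercorrelation; coincident ball centers, uncovered pore voxels, and
  balls covering no voxels are errors with located messages.

## What the synthetic geometries do and do not show

`generate_ball_packing()` grows a connected cluster of overlapping random
balls (each new ball attached to a uniformly chosen existing one at 40–90%
of the radius sum), guaranteeing ball-network connectivity by construction
and resampling until the voxel graph is also a single component; radii stay
≥ 2 voxels so voxelization is non-degenerate, and a porosity target can be
grown to within half a percentage point from below. This emulates the
*structure* the simulations assume — a connected, tortuous, bounded pore
phase with tunable porosity — and is exactly the geometry class for which
ball networks are an honest coarse model.

It does not emulate real soil morphology: no correlated random fields, no
anisotropy, no dead-end micro-porosity below the voxel scale, no
size-distribution tail of a segmented micro-CT image. Passing tests on
these geometries therefore demonstrate correctness of the solvers,
conservation, convergence orders and the learning machinery; they do not by
themselves establish accuracy claims for any particular field soil, which
would require segmented image data.

## Known limitations

* Advective transport is not modeled; the framework is diffusion-only by
  design, valid for saturated, closed systems.
* Two phases only (solid/liquid); partial saturation would need a drainage
  preprocessing step that redistributes liquid and tags the air phase as
  non-interacting solid.
* One microbial functional group, no temperature or moisture response
  functions.
* The ball representation carries an irreducible discretization error:
  learned conductances consistently improve one-interval predictions and
  the diffusively-scaled layer-profile comparison, but at horizons far past
  the training interval the profile mismatch is dominated by the ball
  geometry itself, not by $\theta$.
* Pure-R sparse linear algebra bounds practical problem sizes to a few
  hundred thousand pore voxels; the algorithms themselves are linear-time
  per step in the number of edges.
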