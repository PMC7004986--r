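---
title: "Regularized optimal mass transport for dynamic tracer imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized optimal mass transport for dynamic tracer imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Dynamic contrast-enhanced image series track a tracer whose signal
enhancement behaves like a transported mass. Given two observed volumes
$\mu_\mathrm{init}$ and $\mu_\mathrm{final}$ on a normalized time interval
$t \in [0,1]$, the package recovers the time-varying velocity field $v(t,x)$
that moves the first into the second with minimal kinetic energy,

$$\mathcal R[\mu, v] = \int_0^1 \!\!\int_\Omega \tfrac12\, \mu\,\|v\|^2 \,dx\,dt,$$

subject to the advection--diffusion constraint

$$\partial_t \mu + \nabla\cdot(\mu v) = \nabla\cdot(\sigma^2 \nabla \mu),$$

with isotropic constant diffusivity $D = \sigma^2 I$. This is the dynamic
(Benamou--Brenier) formulation of optimal mass transport, regularized by a
diffusion term: diffusion both smooths the recovered flow and represents the
Fickian component of real tracer transport, so gradient-driven spreading is
not misattributed to bulk flow. The final image is not matched exactly;
it is treated as a noisy observation ($\mu_N + \psi = \mu_\mathrm{final}$
with i.i.d. Gaussian $\psi$), giving the free-endpoint objective

$$\min_v \; \mathcal R[v] \;+\; \xi\,\|\mu_N - \mu_\mathrm{final}\|^2_\Psi ,$$

so observation noise does not force spurious velocity.

### Discretization

Space is a cell-centered grid of $m_1 \times m_2 \times m_3$ cells with
uniform edge $dx$; each image pair is split into $N$ steps of length
$dt = 1/N$. One transport step is the operator splitting

$$(I - dt\,\mathbf D)\,\mu_{n+1} = \mathbf A(v_n)\,\mu_n,$$

where $\mathbf A(v)$ is the particle-in-cell deposition matrix (each cell's
mass is carried by a particle displaced by $v\,dt$ and assigned to the eight
surrounding cell centers by trilinear weights) and $\mathbf D$ is the
7-point Laplacian scaled by $\sigma^2$, inverted by backward Euler. Both
operators have unit column sums, so every step conserves total mass exactly;
both have nonnegative "inverse action" on densities ($\mathbf A$ has
nonnegative entries, $I - dt\,\mathbf D$ is an M-matrix), so nonnegativity
of the interpolated densities is guaranteed structurally rather than
enforced as a constraint. The discrete energy pairs the pre-step density
with its step velocity,
$\tfrac12\,dt\,dx^3 \sum_n \sum_i \mu_{n-1,i} \|v_{n,i}\|^2$; the $\tfrac12$
follows the continuous action, so for a rigid translation of unit mass over
displacement $d$ the minimal objective approaches the Wasserstein-2 action
$\tfrac12\|d\|^2$.

### Choices the continuous formulation leaves open

* **Boundary conditions.** Zero-flux (Neumann) closure for diffusion and
  boundary clamping for advected particles. Both keep all mass in the
  domain, which the mass-balance interpretation of the model requires.
* **Velocity staggering.** Cell-centered components: the simplest layout
  consistent with a per-cell particle push. No staggered grid is needed
  because the scheme never differentiates the velocity.
* **Interpolation order.** Trilinear deposition and interpolation
  everywhere (transport, pathline integration, rasterization), first-order
  accurate in cell size and positivity-preserving.
* **Energy pairing.** The discrete energy uses $\mu_{n-1}$ (the density the
  particles actually carry during step $n$); pairing with $\mu_n$ differs
  only at $O(dt)$.
* **Degenerate axes.** An axis of size 1 simply drops out of every stencil,
  so 2D and 1D problems run unchanged.

## Solving the inverse problem

Because the propagation determines every $\mu_n$ from $v$ and the fixed
initial image, the objective is a function of the velocities alone. It is
minimized by Gauss--Newton from $v = 0$:

* The exact gradient comes from an adjoint (back-propagation) recursion
  through the transport steps; it costs one extra sweep and is verified
  against central finite differences in the test suite (relative error
  below $10^{-4}$).
* The Gauss--Newton Hessian (the energy block, which is diagonal, plus the
  endpoint term $2\xi J^\top \Psi^{-1} J$ with $J$ the sensitivity of
  $\mu_N$) is applied matrix-free; the normal equations are solved by
  preconditioned conjugate gradients (Jacobi preconditioner from the
  energy diagonal plus Levenberg damping, 20--30 inner iterations).
* Backtracking (Armijo) line search guarantees every accepted iterate does
  not increase the objective.
* The endpoint weight is stiff by design (the data term must dominate the
  energy at convergence), which slows plain Gauss--Newton badly. The solver
  therefore approaches it by continuation: a fixed ladder of weights
  ($0.01, 0.1, 1 \times$ the full weight by default), each level
  warm-started from the last. The recorded convergence history carries a
  `level` column; monotonicity holds within a level, since the objective
  being minimized changes between levels.

A note on smoothness: trilinear deposition weights are piecewise linear in
the particle position, so the objective has kinks where particles cross
cell boundaries. At $v = 0$ every particle sits exactly on a kink; the
one-sided gradient used there is a valid descent direction in practice, and
gradient verification is done at random nonzero velocities where the
objective is smooth.

### Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `sigma2` | diffusivity, $dx^2$ per unit normalized time | 0.002 | moderate regularization; sweeps of $\{0, \sigma^2/10, \sigma^2\}$ show the qualitative regimes |
| `xi` | endpoint weight per cell (scaled by cell count internally) | 50 | endpoint term at $v=0$ exceeds the transport energy by orders of magnitude, forcing data fidelity |
| `n_steps` | interpolation steps $N$ per pair | 10 | per-step displacements stay below a voxel for typical inter-frame motion |
| `psi` | endpoint noise covariance scale | 1 | absorbed into `xi` unless noise is calibrated |

The per-cell scaling of `xi` makes the weight independent of grid size for
images of comparable intensity range. Each image pair is solved on its own
normalized interval starting from the *observed* earlier frame (not the
previous pair's free endpoint), so single-pair errors do not accumulate
along the series; physical speeds are recovered by dividing by the real
inter-frame interval at reporting time.

## The Lagrangian layer

The constraint equation in conservation form transports mass with the
*augmented velocity*

$$v^\mathrm{aug} = v - \sigma^2 \nabla \log \mu,$$

which is therefore the field whose integral curves are particle
trajectories. Pathlines seeded at selected voxels are integrated through
the piecewise-in-time augmented field with classical RK4 and trilinear
interpolation, recording speed ($\|v^\mathrm{aug}\|$, the *speedline*) at
every sample. Reported speeds use the augmented field by default — it is
the field actually integrated — with a switch to the bare advective $v$,
since "magnitude of the transport vectors" admits both readings. The
density is floored at $10^{-4}\times\max\mu$ before the log-gradient so
empty regions do not produce singular drift.

Seeds follow the percent-baseline rule: voxels whose signal rises at least
12% over baseline during the series. The default reads "at least 12%
increase throughout the interval" as max-over-frames, because requiring all
frames would exclude every voxel still on its rising phase; the all-frames
reading is available as an option.

Pathlines are then clustered with a single-pass QuickBundles scheme under
the mean direct-flip (MDF) distance on 12-point arc-length resamplings;
clusters smaller than `min_cluster_size` (default 5) at threshold
`cluster_threshold` (default 2 voxel lengths) are discarded as
insignificant — both thresholds are exposed because no canonical values
exist. Surviving pathlines are rasterized back to the grid by trilinear
deposition, giving a binary network map (pathline volume = voxel count, a
proxy for total moving-solute flux) and a deposition-weighted mean speed
map, summarized per anatomical mask.

## Compartmental flux

For two disjoint masks, the oriented boundary is the set of 6-connected
face pairs with axis-aligned unit normals. The total flux through a face is
$j_{AD}\cdot\vec n\,dx^2$ with $j_{AD} = -(\sigma^2\nabla\mu - \mu v)$:
density and velocity face values are arithmetic means of the two adjacent
cells and the normal gradient is the two-point difference. Directed influx
keeps only faces with $j_{AD}\cdot\vec n > 0$, accumulated over solver
steps at mid-interval densities. The advective face flux is a central
approximation while particle-in-cell transport is effectively upwind, so
flux--mass agreement is first-order in cell size at a fixed time but the
bias cancels over a complete crossing; the divergence-theorem check in the
test suite uses a fully transiting smooth blob for that reason.

## Synthetic phantoms

The phantom module generates the study conditions the pipeline is tested
under, with no imaging data:

* **Pure-diffusion phantom** (default $32^3$ grid, source blob sd 3 voxels,
  $\sigma^2_\mathrm{true} = 0.5$ voxel$^2$ per frame interval — the
  physical phantom's diffusivity is not published, so the synthetic value
  is chosen to give clearly visible spreading between frames): a central
  Gaussian evolving by diffusion only. Solving it with matched diffusivity
  yields a nearly advection-free field, while solving with $\sigma^2 = 0$
  forces an irregular radial advection pattern — the discrimination the
  method is designed for.
* **Translation phantom** (blob sd 3 voxels, 2 voxels per frame by
  default): ground truth for direction and speed recovery.
* **Observation noise**: i.i.d. Gaussian per voxel, clipped at zero because
  densities must stay nonnegative; the clipped fraction is recorded.

The forward simulator reuses the same operator-split steps but at finer
time resolution (8 substeps per frame interval by default, against the
solver's $N \le 10$ over the same span), so recovery tests do not invert
the exact forward map. What these phantoms do *not* emulate: MRI physics
(coil sensitivity, relaxivity, motion), spatially varying or anisotropic
diffusivity, and anatomically structured flow. Passing recovery tests
therefore demonstrates correctness of the transport model and optimizer,
not fidelity of any biological conclusion.

## Problem sizes and numerical tolerances

The test-suite and acceptance studies run at desk scale, chosen so each
solve converges in about a minute: transport-action and diffusivity-sweep
solves on $24^3$ grids with $N = 8$, conservation checks on $16^3$,
gradient verification on $6^3$ with $N = 2$, forward-simulation checks on
$32^3$. Mass conservation holds to $10^{-10}$ relative (exactly, up to
sparse-solve tolerance); the direct sparse Cholesky factorization of
$I - dt\,\mathbf D$ is reused across all steps of a solve. Conjugate
gradients stop at $10^{-2}$ relative residual inside Gauss--Newton (the
outer iteration does not need exact inner solves); Levenberg damping is
$10^{-4}$ relative to the energy-diagonal scale. Where a density appears in
a logarithm or denominator it is floored, never regularized by adding mass,
so totals remain exact.

## Known limitations

* Constant isotropic diffusivity only; spatially varying or tensor $D$ is
  out of scope.
* The advection scheme is first-order; sharp fronts blur by deposition
  diffusion of order $f(1-f)$ voxel$^2$ per step, which the inverse solve
  partially re-absorbs into the velocity. Recovered minimal objectives on
  translation problems consequently sit up to ~13% below the continuum
  action at $N = 8$.
* Pairs are solved independently; no temporal regularity is imposed across
  observed frames.
* No source terms: total intensity must be normalized across frames before
  solving, and unbalanced transport is out of scope.
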