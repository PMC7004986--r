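# romt

Regularized optimal mass transport (rOMT) for dynamic contrast-enhanced
image series, with a Lagrangian pathline workflow and compartmental flux
analysis.

## The problem

Serial 3D images of a tracer (e.g. DCE-MRI of a gadolinium tracer moving
through the brain's cerebrospinal/interstitial fluid spaces) show *where*
signal goes, but not the velocity field that carried it — and they cannot by
themselves distinguish bulk (advective) flow from gradient-driven
(diffusive) spreading. This package is for researchers who want to recover a
voxel-level transport field from such series with minimal assumptions: the
only model imposed is the advection–diffusion equation.

Given consecutive volumes μ_init, μ_final (nonnegative "mass"), the package
solves the dynamic optimal-mass-transport problem

    min_v  ∫₀¹∫ ½ μ ‖v‖² dx dt  +  ξ ‖μ_N − μ_final‖²_Ψ
    s.t.   ∂ₜμ + ∇·(μv) = ∇·(σ²∇μ),   μ(0) = μ_init,   μ ≥ 0,

i.e. the Benamou–Brenier kinetic-energy formulation with a diffusion term in
the continuity constraint and a soft (free) endpoint that absorbs
observation noise. Discretization is particle-in-cell advection plus
backward-Euler diffusion (mass-conserving and positivity-preserving by
construction); the velocity sequence is found by Gauss–Newton with adjoint
gradients. A Lagrangian layer then integrates the augmented velocity
v_aug = v − σ²∇log μ into pathlines with per-point speeds ("speedlines"),
clusters them QuickBundles-style under the mean direct-flip distance,
removes insignificant clusters, rasterizes the surviving network back to
the grid, and reports pathline volume and mean speed per anatomical mask.
Advective + diffusive flux j_AD = −(σ²∇μ − μv) can be integrated across
oriented boundaries between compartment masks (e.g. CSF → tissue transfer).

Synthetic phantoms (pure diffusion, constant translation, rotation, with
optional i.i.d. Gaussian observation noise) make the entire pipeline
testable without imaging data.

## Worked example

Recover the flow of a Gaussian blob translated by 3 voxels:

```r
library(romt)

grid <- image_grid(c(24, 24, 24))          # 24^3 voxels, dx = 1
mu0  <- gaussian_blob(grid, center = c(9, 12, 12),  sd = 3, mass = 1)
mu1  <- gaussian_blob(grid, center = c(12, 12, 12), sd = 3, mass = 1)

fit <- romt(mu0, mu1, sigma2 = 0, xi = 50, n_steps = 8,
            control = romt_control(max_iter = 20, cg_iter = 30,
                                   grad_tol = 1e-4))
print(fit)
#> rOMT fit: 1 image pair on a 24 x 24 x 24 grid (dx = 1)
#>   sigma2 = 0, xi = 50, N = 8 steps/pair
#>   objective 3.991 (transport energy 3.626)
```

The minimal objective, 3.99, approximates the Wasserstein-2 action of a
unit-mass translation, ½‖d‖² = 4.5 (the discrete transport scheme
re-absorbs part of its deposition spreading into the velocity, which is why
the discrete optimum sits slightly below the continuum value). Pathlines
seeded inside the blob then travel ~3 voxels at recovered speed ~3 per pair
interval:

```r
seeds <- which(mu0 >= 0.1 * max(mu0))
paths <- integrate_pathlines(fit, seeds)
paths <- cluster_and_filter(paths, min_cluster_size = 5)
summarize_by_mask(rasterize_pathlines(paths, "binary"),
                  rasterize_pathlines(paths, "speed"),
                  list(whole = array(TRUE, grid$dims)))
```

On a pure-diffusion phantom the same solve discriminates transport modes:
with matched diffusivity the recovered advective field is nearly zero,
while forcing σ² = 0 produces a spurious radial flow an order of magnitude
faster — the package's core diagnostic for advection vs diffusion.

For file-based runs, `run_pipeline()` (or `inst/cli/romt.R`) drives
NIfTI-in → preprocess (percent-baseline, intensity normalization,
smoothing) → solve → pathlines → maps/summaries (NIfTI, VTK, CSV) → flux,
with a JSON manifest recording config, seed and output checksums.

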