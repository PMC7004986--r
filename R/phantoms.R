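#' Discretized Gaussian blob
#'
#' An isotropic Gaussian density sampled at cell centers and renormalized so
#' the total mass equals `mass` exactly (compensating truncation at the
#' domain boundary).
#'
#' @param grid an `image_grid`.
#' @param center blob center in voxel coordinates (length 3).
#' @param sd standard deviation in voxels, > 0.
#' @param mass total mass.
#' @param amplitude if given instead of `mass`, scales the blob so its peak
#'   value equals `amplitude`.
#' @return Scalar field.
#' @export
gaussian_blob <- function(grid, center = (grid$dims + 1) / 2, sd = 3,
                          mass = 1, amplitude = NULL) {
  if (sd <= 0) stop("sd must be > 0")
  center <- as.numeric(center)
  if (any(center < 1) || any(center > grid$dims)) stop("center outside grid")
  xyz <- cell_coords(grid)
  r2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  g <- exp(-0.5 * r2 / sd^2)
  if (!is.null(amplitude)) g <- amplitude * g else g <- mass * g / sum(g)
  array(g, grid$dims)
}

#' Named analytic velocity fields
#'
#' Builders for canonical flows used by phantoms and integrator tests, all
#' in world units per unit time.
#'
#' @param grid an `image_grid`.
#' @param u constant velocity vector (length 3).
#' @return Vector field of dim `c(grid$dims, 3)`.
#' @export
constant_field <- function(grid, u) {
  v <- array(0, c(grid$dims, 3L))
  for (c in 1:3) v[, , , c] <- u[c]
  v
}

#' @rdname constant_field
#' @param center rotation center in voxel coordinates.
#' @param omega angular velocity (radians per unit time) about the z axis.
#' @export
rotation_field <- function(grid, center = (grid$dims + 1) / 2, omega = 1) {
  xyz <- cell_coords(grid)
  v <- array(0, c(grid$dims, 3L))
  v[, , , 1] <- array(-omega * (xyz[, 2] - center[2]) * grid$dx, grid$dims)
  v[, , , 2] <- array(omega * (xyz[, 1] - center[1]) * grid$dx, grid$dims)
  v
}

#' Forward advection-diffusion simulation
#'
#' Evolves an initial density with the operator-split transport steps at
#' `substeps` sub-intervals per frame — by default finer time resolution than
#' the inverse solver uses, so solver-recovery tests do not commit an inverse
#' crime. Mass is constant across frames.
#'
#' @param mu0 nonnegative initial scalar field.
#' @param grid an `image_grid`.
#' @param v vector field (constant in time), or NULL for pure diffusion.
#' @param sigma2 true diffusivity (voxel-size units squared per frame
#'   interval when `dx = 1`).
#' @param n_frames number of output frames (>= 2), the first being `mu0`.
#' @param frame_dt simulated time per frame interval.
#' @param substeps simulation steps per frame interval.
#' @param times optional explicit frame times.
#' @return A noise-free `density_series` in raw units.
#' @export
simulate_forward <- function(mu0, grid, v = NULL, sigma2 = 0, n_frames = 5L,
                             frame_dt = 1, substeps = 8L, times = NULL) {
  check_scalar_field(mu0, grid, nonneg = TRUE, name = "mu0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (substeps < 1L) stop("substeps must be >= 1")
  if (is.null(v)) v <- zero_vector_field(grid)
  check_vector_field(v, grid)
  h <- frame_dt / substeps
  disp <- max(abs(v)) * h / grid$dx
  if (disp > 1) {
    warning(sprintf("per-substep displacement %.2f voxels exceeds 1; increase substeps", disp))
  }
  diffuser <- make_diffuser(grid, sigma2, h)
  frames <- vector("list", n_frames)
  frames[[1L]] <- mu0
  cur <- as.numeric(mu0)
  A <- pic_matrices(grid, v, h)$A
  for (k in 2:n_frames) {
    for (s in seq_len(substeps)) {
      cur <- diffuser$solve(as.numeric(A %*% cur))
      cur[cur < 0] <- 0
    }
    frames[[k]] <- array(cur, grid$dims)
  }
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * frame_dt
  density_series(frames, times = times, grid = grid, units = "raw")
}

#' Pure-diffusion phantom
#'
#' A central Gaussian source evolving by diffusion only — the synthetic
#' analogue of a microdialysis agar diffusion experiment. The canonical
#' input for checking that solving with matched diffusivity yields a nearly
#' advection-free flow field while forcing `sigma2 = 0` produces spurious
#' advection.
#'
#' @param grid an `image_grid` (default 32^3 voxels).
#' @param center,sd,mass source blob parameters (see [gaussian_blob()]).
#' @param sigma2_true diffusivity driving the simulation.
#' @param n_frames,frame_dt,substeps simulation controls
#'   (see [simulate_forward()]).
#' @return A noise-free `density_series`.
#' @export
make_diffusion_phantom <- function(grid = image_grid(c(32, 32, 32)),
                                   center = (grid$dims + 1) / 2, sd = 3,
                                   mass = 1, sigma2_true = 0.5, n_frames = 5L,
                                   frame_dt = 1, substeps = 8L) {
  mu0 <- gaussian_blob(grid, center = center, sd = sd, mass = mass)
  simulate_forward(mu0, grid, v = NULL, sigma2 = sigma2_true,
                   n_frames = n_frames, frame_dt = frame_dt,
                   substeps = substeps)
}

#' Constant-translation phantom
#'
#' A Gaussian blob advected at constant velocity (optionally with mild
#' diffusion), the ground-truth input for direction/speed recovery tests.
#'
#' @param grid an `image_grid`.
#' @param center initial blob center (voxel coordinates).
#' @param sd blob standard deviation in voxels.
#' @param mass blob mass.
#' @param shift displacement per frame interval, world units (length 3).
#' @param sigma2_true diffusivity of the simulation.
#' @param n_frames,substeps simulation controls.
#' @param background constant background intensity added to every frame.
#' @return A noise-free `density_series` with attribute `"v_true"`.
#' @export
make_translation_phantom <- function(grid = image_grid(c(24, 24, 24)),
                                     center = c(8, 12, 12), sd = 3, mass = 1,
                                     shift = c(2, 0, 0), sigma2_true = 0.02,
                                     n_frames = 3L, substeps = 8L,
                                     background = 0) {
  mu0 <- gaussian_blob(grid, center = center, sd = sd, mass = mass) + background
  v <- constant_field(grid, shift)
  out <- simulate_forward(mu0, grid, v = v, sigma2 = sigma2_true,
                          n_frames = n_frames, substeps = substeps)
  attr(out, "v_true") <- shift
  out
}

#' Add i.i.d. Gaussian observation noise to a series
#'
#' Adds independent Gaussian noise per voxel and clips at zero (densities
#' must stay nonnegative); the clipped-voxel fraction is attached as
#' attribute `"clipped_fraction"`. Deterministic for a fixed seed.
#'
#' @param series a `density_series`.
#' @param noise_sd noise standard deviation, >= 0.
#' @param seed RNG seed.
#' @return The noisy series.
#' @export
add_noise <- function(series, noise_sd, seed = 1L) {
  stopifnot(inherits(series, "density_series"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(series)
  set.seed(seed)
  clipped <- 0L
  total <- 0L
  out <- series
  out$frames <- lapply(series$frames, function(f) {
    g <- f + array(stats::rnorm(length(f), sd = noise_sd), dim(f))
    clipped <<- clipped + sum(g < 0)
    total <<- total + length(g)
    g[g < 0] <- 0
    g
  })
  attr(out, "clipped_fraction") <- clipped / total
  out
}

#' Second moments of a density field
#'
#' Center of mass and per-axis variance in voxel coordinates; the oracle for
#' heat-kernel variance growth (`s^2(t) = s0^2 + 2 sigma2 t`) and transport
#' displacement checks.
#'
#' @param mu nonnegative scalar field.
#' @param grid an `image_grid`.
#' @return List with `center` (length 3) and `variance` (length 3).
#' @export
field_moments <- function(mu, grid) {
  check_scalar_field(mu, grid, nonneg = TRUE)
  w <- as.numeric(mu)
  tot <- sum(w)
  if (tot <= 0) return(list(center = rep(NA_real_, 3), variance = rep(NA_real_, 3)))
  xyz <- cell_coords(grid)
  ctr <- colSums(xyz * w) / tot
  va <- colSums(sweep(xyz, 2, ctr)^2 * w) / tot
  list(center = ctr, variance = va)
}
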