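#' Cell-centered image grid
#'
#' Defines the shared geometric frame for all fields: a cell-centered 3D
#' lattice of `dims = c(m1, m2, m3)` voxels with uniform edge length `dx`
#' (world units, e.g. mm) and a voxel-to-world affine. Cell centers sit at
#' voxel coordinates `1..m` along each axis; the voxel-to-world map follows
#' the NIfTI convention (0-based voxel indices).
#'
#' @param dims integer vector of length 3 (each >= 1).
#' @param dx uniform voxel edge length, > 0.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(dx, dx, dx, 1))`.
#' @return An object of class `"image_grid"` with elements `dims`, `dx`,
#'   `affine` and `n_cells`.
#' @export
image_grid <- function(dims, dx = 1, affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("dims must be three integers, all >= 1")
  }
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("dx must be a positive scalar")
  if (is.null(affine)) affine <- diag(c(dx, dx, dx, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be an invertible 4x4 matrix")
  }
  structure(list(dims = dims, dx = dx, affine = affine,
                 n_cells = prod(dims)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d cells, dx = %g\n",
              x$dims[1], x$dims[2], x$dims[3], x$dx))
  invisible(x)
}

check_scalar_field <- function(f, grid, nonneg = FALSE, name = "field") {
  if (!is.array(f) || !identical(dim(f), as.integer(grid$dims))) {
    stop(sprintf("%s must be an array with dim equal to grid dims", name))
  }
  if (!all(is.finite(f))) stop(sprintf("%s contains non-finite values", name))
  if (nonneg && any(f < 0)) stop(sprintf("%s must be nonnegative", name))
  invisible(TRUE)
}

check_vector_field <- function(v, grid, name = "velocity") {
  if (!is.array(v) || length(dim(v)) != 4L ||
      !identical(dim(v)[1:3], as.integer(grid$dims)) || dim(v)[4] != 3L) {
    stop(sprintf("%s must be an array with dim c(grid dims, 3)", name))
  }
  if (!all(is.finite(v))) stop(sprintf("%s contains non-finite values", name))
  invisible(TRUE)
}

zero_vector_field <- function(grid) array(0, c(grid$dims, 3L))

#' Voxel-to-world and world-to-voxel coordinate maps
#'
#' Voxel coordinates are 1-based continuous cell-center coordinates; the
#' affine acts on 0-based indices per the NIfTI convention.
#'
#' @param grid an `image_grid`.
#' @param x numeric matrix with one coordinate triple per row.
#' @return Matrix of mapped coordinates, one row per input row.
#' @export
voxel_to_world <- function(grid, x) {
  x <- rbind_coords(x)
  h <- cbind(x - 1, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, x) {
  x <- rbind_coords(x)
  h <- cbind(x, 1)
  out <- h %*% t(solve(grid$affine))
  out[, 1:3, drop = FALSE] + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.matrix(x)
}

# Index an array along one axis without losing dimensions.
index_axis <- function(f, axis, idx) {
  args <- rep(list(quote(expr = )), 3L)
  args[[axis]] <- idx
  do.call(`[`, c(list(f), args, list(drop = FALSE)))
}

#' Cell-centered discrete gradient
#'
#' Central differences in the interior, one-sided differences at boundary
#' faces, scaled by `1/dx`. An axis with a single cell contributes a zero
#' component; such axes are recorded in the `"degenerate_axes"` attribute.
#'
#' @param f scalar field (3D array on `grid`).
#' @param grid an `image_grid`.
#' @return Vector field: array of dim `c(grid$dims, 3)`.
#' @export
gradient_field <- function(f, grid) {
  check_scalar_field(f, grid)
  out <- array(0, c(grid$dims, 3L))
  degenerate <- integer(0)
  for (a in 1:3) {
    m <- grid$dims[a]
    if (m == 1L) {
      degenerate <- c(degenerate, a)
      next
    }
    ip <- pmin(seq_len(m) + 1L, m)
    im <- pmax(seq_len(m) - 1L, 1L)
    num <- index_axis(f, a, ip) - index_axis(f, a, im)
    h <- (ip - im) * grid$dx            # 2dx interior, dx at the two ends
    out[, , , a] <- sweep(num, a, h, "/")
  }
  if (length(degenerate)) attr(out, "degenerate_axes") <- degenerate
  out
}

lap1d <- function(m) {
  if (m == 1L) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(1, 1)))
  d <- c(-1, rep(-2, max(m - 2L, 0L)), -1)
  Matrix::bandSparse(m, k = c(-1L, 0L, 1L),
                     diagonals = list(rep(1, m - 1L), d, rep(1, m - 1L)),
                     symmetric = FALSE)
}

#' Discrete diffusion operator
#'
#' The 7-point Laplacian with zero-flux (Neumann) boundary closure, scaled by
#' the isotropic diffusivity `sigma2` and `1/dx^2`: a sparse `M x M` matrix
#' representing `div(sigma2 grad)`. It is symmetric, negative semidefinite,
#' and annihilates constant fields, so backward-Euler diffusion conserves
#' total mass. An axis of size 1 contributes no coupling (the operator acts
#' in 2D/1D automatically).
#'
#' @param grid an `image_grid`.
#' @param sigma2 isotropic diffusivity, >= 0.
#' @return A sparse symmetric matrix of dimension `n_cells x n_cells`.
#' @export
diffusion_operator <- function(grid, sigma2 = 1) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  m <- grid$dims
  I1 <- Matrix::Diagonal(m[1]); I2 <- Matrix::Diagonal(m[2]); I3 <- Matrix::Diagonal(m[3])
  L <- Matrix::kronecker(I3, Matrix::kronecker(I2, lap1d(m[1]))) +
    Matrix::kronecker(I3, Matrix::kronecker(lap1d(m[2]), I1)) +
    Matrix::kronecker(lap1d(m[3]), Matrix::kronecker(I2, I1))
  (sigma2 / grid$dx^2) * L
}

# Backward-Euler diffusion solver: factorizes (I - dt * sigma2 * L) once so a
# solver run can reuse it for every propagation step.
make_diffuser <- function(grid, sigma2, dt) {
  if (sigma2 <= 0 || dt <= 0) {
    return(list(identity = TRUE, solve = function(x) x))
  }
  L <- diffusion_operator(grid, sigma2)
  B <- Matrix::Diagonal(grid$n_cells) - dt * L
  B <- Matrix::forceSymmetric(B)
  ch <- Matrix::Cholesky(B, LDL = FALSE)
  list(identity = FALSE,
       B = B,
       solve = function(x) as.numeric(Matrix::solve(ch, x, system = "A")))
}

#' Backward-Euler (implicit) diffusion step
#'
#' Solves `(I - dt * sigma2 * L) mu' = mu` with the Neumann closure.
#' Total mass is conserved and nonnegativity is preserved (the system matrix
#' is an M-matrix); solver-tolerance negatives are clipped to zero.
#'
#' @param mu scalar field (3D array), nonnegative for density inputs.
#' @param grid an `image_grid`.
#' @param sigma2 isotropic diffusivity, >= 0.
#' @param dt time step, > 0.
#' @return Diffused scalar field.
#' @export
implicit_diffuse <- function(mu, grid, sigma2, dt) {
  check_scalar_field(mu, grid)
  if (dt <= 0) stop("dt must be > 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (sigma2 == 0) return(mu)
  dif <- make_diffuser(grid, sigma2, dt)
  out <- dif$solve(as.numeric(mu))
  resid <- sqrt(sum((as.numeric(dif$B %*% out) - as.numeric(mu))^2))
  if (!all(is.finite(out)) || resid > 1e-6 * max(1, sqrt(sum(mu^2)))) {
    stop(sprintf("implicit diffusion solve failed (residual %.3e)", resid))
  }
  if (min(mu) >= 0) out[out < 0] <- 0
  array(out, grid$dims)
}

# Cell-center voxel coordinates of every cell, as an M x 3 matrix
# (column-major linear order, axis 1 fastest).
cell_coords <- function(grid) {
  m <- grid$dims
  cbind(rep(seq_len(m[1]), times = m[2] * m[3]),
        rep(rep(seq_len(m[2]), each = m[1]), times = m[3]),
        rep(seq_len(m[3]), each = m[1] * m[2]))
}

# Particle-in-cell deposition matrices. Every cell center is displaced by
# v * dt (converted to voxel units) and its mass deposited to the 8
# surrounding cell centers by trilinear weights; displaced positions are
# clamped to the domain so mass cannot leave. Returns the deposition matrix
# A(v) (columns sum to 1) and, if `deriv`, the three matrices D_c with
# entries d w_ji / d v_{i,c} (the per-particle weight sensitivities, zero
# where the clamp is active or the axis is degenerate).
pic_matrices <- function(grid, v, dt, deriv = FALSE) {
  check_vector_field(v, grid)
  m <- grid$dims
  M <- grid$n_cells
  scale <- dt / grid$dx
  p <- cell_coords(grid) + matrix(v, nrow = M) * scale
  lo <- matrix(rep(1, 3), nrow = M, ncol = 3, byrow = TRUE)
  hi <- matrix(m, nrow = M, ncol = 3, byrow = TRUE)
  clamped <- p < lo | p > hi
  p <- pmin(pmax(p, lo), hi)

  i0 <- matrix(0L, M, 3); fr <- matrix(0, M, 3)
  for (c in 1:3) {
    if (m[c] == 1L) {
      i0[, c] <- 1L; fr[, c] <- 0
    } else {
      i0[, c] <- pmin(floor(p[, c]), m[c] - 1L)
      fr[, c] <- p[, c] - i0[, c]
    }
  }

  cols <- rep(seq_len(M), 8L)
  rows <- integer(8L * M)
  wts <- numeric(8L * M)
  if (deriv) dw <- list(numeric(8L * M), numeric(8L * M), numeric(8L * M))
  corner <- 0L
  for (b3 in 0:1) for (b2 in 0:1) for (b1 in 0:1) {
    corner <- corner + 1L
    b <- c(b1, b2, b3)
    w1 <- if (b1 == 1L) fr[, 1] else 1 - fr[, 1]
    w2 <- if (b2 == 1L) fr[, 2] else 1 - fr[, 2]
    w3 <- if (b3 == 1L) fr[, 3] else 1 - fr[, 3]
    j1 <- pmin(i0[, 1] + b1, m[1]); j2 <- pmin(i0[, 2] + b2, m[2]); j3 <- pmin(i0[, 3] + b3, m[3])
    seg <- (corner - 1L) * M + seq_len(M)
    rows[seg] <- j1 + (j2 - 1L) * m[1] + (j3 - 1L) * m[1] * m[2]
    wts[seg] <- w1 * w2 * w3
    if (deriv) {
      s1 <- if (b1 == 1L) 1 else -1
      s2 <- if (b2 == 1L) 1 else -1
      s3 <- if (b3 == 1L) 1 else -1
      d1 <- s1 * w2 * w3; d2 <- w1 * s2 * w3; d3 <- w1 * w2 * s3
      d1[clamped[, 1] | m[1] == 1L] <- 0
      d2[clamped[, 2] | m[2] == 1L] <- 0
      d3[clamped[, 3] | m[3] == 1L] <- 0
      dw[[1]][seg] <- d1 * scale
      dw[[2]][seg] <- d2 * scale
      dw[[3]][seg] <- d3 * scale
    }
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = wts, dims = c(M, M))
  out <- list(A = A)
  if (deriv) {
    out$D <- lapply(dw, function(x)
      Matrix::sparseMatrix(i = rows, j = cols, x = x, dims = c(M, M)))
  }
  out
}

#' Particle-in-cell advection step
#'
#' Carries each cell's mass along the cell-centered velocity for one time
#' step and deposits it to neighboring cell centers by trilinear weights,
#' i.e. applies the averaging matrix `A(v)`. Total mass is conserved exactly
#' and nonnegativity is preserved; particles displaced outside the domain are
#' clamped to the boundary.
#'
#' @param mu nonnegative scalar field (3D array).
#' @param v cell-centered vector field, world units per unit time.
#' @param grid an `image_grid`.
#' @param dt time step.
#' @return Advected scalar field.
#' @export
pic_advect <- function(mu, v, grid, dt) {
  check_scalar_field(mu, grid)
  check_vector_field(v, grid)
  A <- pic_matrices(grid, v, dt)$A
  array(as.numeric(A %*% as.numeric(mu)), grid$dims)
}

# Trilinear interpolation of a scalar (3D) or vector (4D) field at continuous
# voxel coordinates (rows of pts), with clamped extension outside the domain.
interp_field <- function(f, grid, pts) {
  m <- grid$dims
  n <- nrow(pts)
  lo <- matrix(1, n, 3); hi <- matrix(m, n, 3, byrow = TRUE)
  p <- pmin(pmax(pts, lo), hi)
  i0 <- matrix(0L, n, 3); fr <- matrix(0, n, 3)
  for (c in 1:3) {
    if (m[c] == 1L) { i0[, c] <- 1L; fr[, c] <- 0 }
    else { i0[, c] <- pmin(floor(p[, c]), m[c] - 1L); fr[, c] <- p[, c] - i0[, c] }
  }
  ncomp <- if (length(dim(f)) == 4L) dim(f)[4] else 1L
  fm <- matrix(f, nrow = prod(m), ncol = ncomp)
  out <- matrix(0, n, ncomp)
  for (b3 in 0:1) for (b2 in 0:1) for (b1 in 0:1) {
    w <- (if (b1 == 1L) fr[, 1] else 1 - fr[, 1]) *
      (if (b2 == 1L) fr[, 2] else 1 - fr[, 2]) *
      (if (b3 == 1L) fr[, 3] else 1 - fr[, 3])
    j <- pmin(i0[, 1] + b1, m[1]) +
      (pmin(i0[, 2] + b2, m[2]) - 1L) * m[1] +
      (pmin(i0[, 3] + b3, m[3]) - 1L) * m[1] * m[2]
    out <- out + w * fm[j, , drop = FALSE]
  }
  out
}
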