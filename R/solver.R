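#' Solver control parameters
#'
#' Numerical controls for the Gauss-Newton rOMT solve. The model parameters
#' themselves (diffusivity `sigma2`, endpoint weight `xi`, step count
#' `n_steps`, noise scale `psi`) are arguments of [romt()].
#'
#' @param max_iter Gauss-Newton iteration cap.
#' @param grad_tol relative gradient-norm tolerance: iteration stops once the
#'   gradient norm falls below `grad_tol` times its value at `v = 0`.
#' @param cg_iter inner conjugate-gradient iteration cap for the
#'   Gauss-Newton normal equations (matrix-free).
#' @param cg_tol relative residual tolerance for the inner CG solve.
#' @param ls_max maximum number of backtracking (Armijo) halvings.
#' @param damping Levenberg-style diagonal damping added to the
#'   Gauss-Newton Hessian, relative to `dt * dx^3 * max(mu_init)`.
#' @param xi_levels continuation ladder for the endpoint weight: fractions of
#'   the full weight solved in sequence with warm starts, easing the stiff
#'   penalty in gradually (1 is always included as the final level).
#' @return A list of class `"romt_control"`.
#' @export
romt_control <- function(max_iter = 20L, grad_tol = 1e-3, cg_iter = 20L,
                         cg_tol = 1e-2, ls_max = 25L, damping = 1e-4,
                         xi_levels = c(0.01, 0.1, 1)) {
  structure(list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 cg_iter = as.integer(cg_iter), cg_tol = cg_tol,
                 ls_max = as.integer(ls_max), damping = damping,
                 xi_levels = xi_levels),
            class = "romt_control")
}

# Forward propagation in linearized form. mu0 is a length-M vector, v an
# array c(M, 3, N). Returns the N+1 density vectors and, on request, the
# per-step deposition matrices and their velocity sensitivities.
propagate_core <- function(mu0, v, grid, dt, diffuser, deriv = FALSE) {
  N <- dim(v)[3]
  mus <- vector("list", N + 1L)
  mus[[1L]] <- mu0
  Alist <- if (deriv) vector("list", N) else NULL
  Dlist <- if (deriv) vector("list", N) else NULL
  for (n in seq_len(N)) {
    vn <- array(v[, , n], c(grid$dims, 3L))
    pm <- pic_matrices(grid, vn, dt, deriv = deriv)
    adv <- as.numeric(pm$A %*% mus[[n]])
    nxt <- diffuser$solve(adv)
    if (!all(is.finite(nxt))) {
      stop(sprintf("non-finite density produced at propagation step %d", n))
    }
    nxt[nxt < 0] <- 0  # M-matrix property makes these solver-noise only
    mus[[n + 1L]] <- nxt
    if (deriv) { Alist[[n]] <- pm$A; Dlist[[n]] <- pm$D }
  }
  list(mus = mus, A = Alist, D = Dlist)
}

#' Propagate a density forward under a velocity sequence
#'
#' Applies the operator-split transport recursion
#' `mu_{n+1} = (I - dt D)^{-1} A(v_n) mu_n` for `n = 0..N-1`: particle-in-cell
#' advection followed by backward-Euler diffusion. Total mass is conserved
#' and nonnegativity preserved at every step.
#'
#' @param mu_init nonnegative scalar field (3D array).
#' @param velocities array of dim `c(grid$dims, 3, N)` (or a list of N
#'   vector fields).
#' @param grid an `image_grid`.
#' @param sigma2 isotropic diffusivity.
#' @param dt time step; defaults to `1/N` so the pair spans normalized time
#'   `[0, 1]`.
#' @return List of `N + 1` scalar fields `mu_0 .. mu_N`.
#' @export
forward_propagate <- function(mu_init, velocities, grid, sigma2 = 0,
                              dt = NULL) {
  check_scalar_field(mu_init, grid, nonneg = TRUE, name = "mu_init")
  v <- as_velocity_array(velocities, grid)
  N <- dim(v)[3]
  if (is.null(dt)) dt <- 1 / N
  diffuser <- make_diffuser(grid, sigma2, dt)
  fw <- propagate_core(as.numeric(mu_init), v, grid, dt, diffuser)
  lapply(fw$mus, array, dim = grid$dims)
}

as_velocity_array <- function(velocities, grid) {
  M <- grid$n_cells
  if (is.list(velocities)) {
    for (vn in velocities) check_vector_field(vn, grid)
    v <- array(0, c(M, 3L, length(velocities)))
    for (n in seq_along(velocities)) v[, , n] <- matrix(velocities[[n]], M, 3L)
    return(v)
  }
  d <- dim(velocities)
  if (length(d) == 4L) {
    check_vector_field(velocities, grid)
    return(array(velocities, c(M, 3L, 1L)))
  }
  if (length(d) == 5L) {
    stopifnot(identical(d[1:3], as.integer(grid$dims)), d[4] == 3L)
    if (!all(is.finite(velocities))) stop("velocities contain non-finite values")
    return(array(velocities, c(M, 3L, d[5])))
  }
  if (length(d) == 3L && d[1] == M && d[2] == 3L) return(velocities)
  stop("velocities must be an array c(dims, 3, N) or a list of vector fields")
}

#' Discrete transport energy
#'
#' The kinetic-energy cost `0.5 * dt * dx^3 * sum_n sum_cells
#' mu_{n-1} * |v_n|^2`, the discretization of the Benamou-Brenier action
#' `int int 0.5 mu |v|^2`. It is nonnegative and zero iff the velocity
#' vanishes on the support of the density.
#'
#' @param mu list of `N + 1` scalar fields (or the output of
#'   [forward_propagate()]).
#' @param velocities N velocity fields (array `c(dims, 3, N)` or list).
#' @param grid an `image_grid`.
#' @param dt time step; defaults to `1/N`.
#' @return Scalar energy.
#' @export
transport_energy <- function(mu, velocities, grid, dt = NULL) {
  v <- as_velocity_array(velocities, grid)
  N <- dim(v)[3]
  if (length(mu) != N + 1L) stop("need N + 1 density fields for N velocities")
  if (is.null(dt)) dt <- 1 / N
  e <- 0
  for (n in seq_len(N)) {
    mun <- as.numeric(mu[[n]])
    if (any(mun < 0)) stop("densities must be nonnegative")
    e <- e + sum(mun * rowSums(matrix(v[, , n], ncol = 3L)^2))
  }
  0.5 * dt * grid$dx^3 * e
}

# Objective value; optionally its exact gradient by the adjoint recursion.
objective_core <- function(v, mu0, muf, grid, dt, diffuser, w_mis,
                           gradient = FALSE) {
  N <- dim(v)[3]
  dx3 <- grid$dx^3
  fw <- propagate_core(mu0, v, grid, dt, diffuser, deriv = gradient)
  mus <- fw$mus
  energy <- 0
  s <- vector("list", N)
  for (n in seq_len(N)) {
    s[[n]] <- rowSums(matrix(v[, , n], ncol = 3L)^2)
    energy <- energy + sum(mus[[n]] * s[[n]])
  }
  energy <- 0.5 * dt * dx3 * energy
  r <- mus[[N + 1L]] - muf
  misfit <- w_mis * sum(r^2)
  out <- list(value = energy + misfit, energy = energy, misfit = misfit,
              mus = mus)
  if (gradient) {
    g <- array(0, dim(v))
    lam <- 2 * w_mis * r
    for (n in N:1) {
      y <- diffuser$solve(lam)
      for (c in 1:3) {
        g[, c, n] <- dt * dx3 * mus[[n]] * v[, c, n] +
          mus[[n]] * as.numeric(Matrix::crossprod(fw$D[[n]][[c]], y))
      }
      if (n > 1L) {
        lam <- 0.5 * dt * dx3 * s[[n]] + as.numeric(Matrix::crossprod(fw$A[[n]], y))
      }
    }
    out$gradient <- g
    out$A <- fw$A
    out$D <- fw$D
  }
  out
}

#' Free-endpoint rOMT objective
#'
#' Propagates `mu_init` forward under `velocities` and evaluates the
#' regularized OMT objective: transport energy plus the endpoint misfit
#' `xi * n_cells / psi * ||mu_N - mu_final||^2`. The exact gradient with
#' respect to the velocities (computed by the adjoint recursion) is attached
#' as attribute `"gradient"` when `gradient = TRUE`.
#'
#' @param velocities N velocity fields.
#' @param mu_init,mu_final nonnegative scalar fields on `grid`.
#' @param grid an `image_grid`.
#' @param sigma2 diffusivity.
#' @param xi endpoint-fit weight (per cell; scaled internally by the cell
#'   count).
#' @param psi scalar noise covariance of the endpoint model.
#' @param dt time step; defaults to `1/N`.
#' @param gradient if TRUE, attach the exact gradient.
#' @return Scalar objective with attributes `"energy"`, `"misfit"` and
#'   optionally `"gradient"` (array `c(dims, 3, N)`).
#' @export
romt_objective <- function(velocities, mu_init, mu_final, grid,
                           sigma2 = 0.002, xi = 50, psi = 1, dt = NULL,
                           gradient = FALSE) {
  check_scalar_field(mu_init, grid, nonneg = TRUE, name = "mu_init")
  check_scalar_field(mu_final, grid, nonneg = TRUE, name = "mu_final")
  v <- as_velocity_array(velocities, grid)
  N <- dim(v)[3]
  if (is.null(dt)) dt <- 1 / N
  diffuser <- make_diffuser(grid, sigma2, dt)
  w_mis <- xi * grid$n_cells / psi
  ob <- objective_core(v, as.numeric(mu_init), as.numeric(mu_final), grid,
                       dt, diffuser, w_mis, gradient = gradient)
  out <- ob$value
  attr(out, "energy") <- ob$energy
  attr(out, "misfit") <- ob$misfit
  if (gradient) {
    g <- array(0, c(grid$dims, 3L, N))
    for (n in seq_len(N)) g[, , , , n] <- array(ob$gradient[, , n], c(grid$dims, 3L))
    attr(out, "gradient") <- g
  }
  out
}

# Matrix-free preconditioned conjugate gradients on the Gauss-Newton normal
# equations; prec is the (positive) diagonal preconditioner.
cg_solve <- function(hv, b, max_iter, tol, prec = NULL) {
  x <- numeric(length(b))
  r <- b
  b0 <- sqrt(sum(r^2))
  if (b0 == 0) return(x)
  z <- if (is.null(prec)) r else r / prec
  p <- z
  rz <- sum(r * z)
  for (k in seq_len(max_iter)) {
    hp <- hv(p)
    alpha <- rz / sum(p * hp)
    if (!is.finite(alpha) || alpha <= 0) break
    x <- x + alpha * p
    r <- r - alpha * hp
    if (sqrt(sum(r^2)) <= tol * b0) break
    z <- if (is.null(prec)) r else r / prec
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

# Gauss-Newton solve for one image pair, with continuation on the endpoint
# weight: the stiff penalty is approached through a fixed ladder of weights
# (control$xi_levels), warm-starting each level from the previous optimum.
# All inputs linearized.
gauss_newton_pair <- function(mu0, muf, grid, sigma2, xi, psi, N, control,
                              verbose = FALSE) {
  M <- grid$n_cells
  dt <- 1 / N
  dx3 <- grid$dx^3
  diffuser <- make_diffuser(grid, sigma2, dt)
  w_full <- xi * M / psi
  damp <- control$damping * dt * dx3 * max(mu0, 1e-12)

  v <- array(0, c(M, 3L, N))
  hist <- NULL
  flag <- "converged"
  levels <- sort(unique(c(control$xi_levels, 1)))
  for (l in seq_along(levels)) {
    last <- l == length(levels)
    res <- gn_level(v, mu0, muf, grid, dt, dx3, diffuser,
                    w_full * levels[l], damp, control,
                    max_iter = if (last) control$max_iter
                               else max(2L, control$max_iter %/% 2L),
                    grad_tol = if (last) control$grad_tol
                               else 10 * control$grad_tol,
                    verbose = verbose)
    v <- res$v
    res$hist$level <- levels[l]
    hist <- rbind(hist, res$hist)
    if (last) { ob <- res$ob; flag <- res$flag; iter <- res$iter }
  }

  list(v = v, mus = ob$mus, objective = ob$value, energy = ob$energy,
       misfit = ob$misfit, iterations = iter, convergence = hist, flag = flag)
}

# One continuation level of the Gauss-Newton iteration.
gn_level <- function(v, mu0, muf, grid, dt, dx3, diffuser, w_mis, damp,
                     control, max_iter, grad_tol, verbose = FALSE) {
  M <- grid$n_cells
  N <- dim(v)[3]
  ob <- objective_core(v, mu0, muf, grid, dt, diffuser, w_mis, gradient = TRUE)
  g0_norm <- sqrt(sum(ob$gradient^2))
  hist <- data.frame(iter = 0L, objective = ob$value, energy = ob$energy,
                     misfit = ob$misfit, grad_norm = g0_norm, step = NA_real_)
  flag <- "converged"
  iter <- 0L
  while (iter < max_iter) {
    gnorm <- sqrt(sum(ob$gradient^2))
    if (gnorm <= grad_tol * max(g0_norm, .Machine$double.eps)) break
    iter <- iter + 1L

    mus <- ob$mus; Alist <- ob$A; Dlist <- ob$D
    hv <- function(u) {
      u <- array(u, c(M, 3L, N))
      out <- array(0, c(M, 3L, N))
      # linearized forward: J u
      delta <- numeric(M)
      for (n in seq_len(N)) {
        rhs <- as.numeric(Alist[[n]] %*% delta)
        for (c in 1:3) {
          rhs <- rhs + as.numeric(Dlist[[n]][[c]] %*% (mus[[n]] * u[, c, n]))
        }
        delta <- diffuser$solve(rhs)
      }
      if (!all(is.finite(delta))) stop("non-finite value in Hessian-vector product")
      # adjoint: J^T (2 w_mis J u), plus the energy block and damping
      lam <- 2 * w_mis * delta
      for (n in N:1) {
        y <- diffuser$solve(lam)
        for (c in 1:3) {
          out[, c, n] <- out[, c, n] +
            mus[[n]] * as.numeric(Matrix::crossprod(Dlist[[n]][[c]], y)) +
            dt * dx3 * mus[[n]] * u[, c, n] + damp * u[, c, n]
        }
        if (n > 1L) lam <- as.numeric(Matrix::crossprod(Alist[[n]], y))
      }
      as.numeric(out)
    }
    # Jacobi preconditioner: the exact diagonal of the smooth quadratic part
    # (energy block plus damping).
    prec <- array(0, c(M, 3L, N))
    for (n in seq_len(N)) {
      pn <- dt * dx3 * mus[[n]] + damp
      for (c in 1:3) prec[, c, n] <- pn
    }
    p <- cg_solve(hv, -as.numeric(ob$gradient), control$cg_iter, control$cg_tol,
                  prec = as.numeric(prec))
    p <- array(p, c(M, 3L, N))
    slope <- sum(ob$gradient * p)
    if (!is.finite(slope) || slope >= 0) { flag <- "no_descent"; break }

    alpha <- 1
    accepted <- FALSE
    for (ls in seq_len(control$ls_max)) {
      trial_v <- v + alpha * p
      trial <- objective_core(trial_v, mu0, muf, grid, dt, diffuser, w_mis)
      if (trial$value <= ob$value + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { flag <- "line_search_exhausted"; break }
    v <- v + alpha * p
    ob <- objective_core(v, mu0, muf, grid, dt, diffuser, w_mis, gradient = TRUE)
    hist <- rbind(hist, data.frame(iter = iter, objective = ob$value,
                                   energy = ob$energy, misfit = ob$misfit,
                                   grad_norm = sqrt(sum(ob$gradient^2)),
                                   step = alpha))
    if (verbose) {
      message(sprintf("  GN %2d (w %.3g): obj %.6e (energy %.4e, misfit %.4e) step %.3g",
                      iter, w_mis, ob$value, ob$energy, ob$misfit, alpha))
    }
  }
  if (iter >= max_iter && flag == "converged") flag <- "max_iter"
  list(v = v, ob = ob, hist = hist, flag = flag, iter = iter)
}

#' Fit the regularized optimal mass transport model
#'
#' Solves the free-endpoint rOMT inverse problem for each consecutive pair of
#' observed images: find the velocity sequence `v_1..v_N` minimizing the
#' transport energy plus a soft endpoint misfit, subject to the discrete
#' advection-diffusion propagation (particle-in-cell advection, backward-Euler
#' diffusion). Each pair is mapped to normalized time `[0, 1]` and solved by a
#' Gauss-Newton method with matrix-free conjugate-gradient inner solves and
#' Armijo backtracking, starting from `v = 0`; accepted iterates never
#' increase the objective. Nonnegativity of the interpolated densities is
#' guaranteed structurally by the transport scheme.
#'
#' @param x a `density_series` (see [density_series()]) with at least two
#'   frames, or a single nonnegative 3D array `mu_init`.
#' @param mu_final when `x` is a single array: the final image.
#' @param grid an `image_grid`; taken from `x` when it is a series.
#' @param sigma2 isotropic diffusivity of the constraint equation
#'   (default 0.002).
#' @param xi endpoint-fit weight per cell (scaled internally by the cell
#'   count so the data term dominates the energy at convergence).
#' @param n_steps number N of interpolation steps per image pair
#'   (`dt = 1/N`).
#' @param psi scalar noise covariance of the endpoint model.
#' @param control a [romt_control()] list.
#' @param verbose print per-iteration diagnostics.
#' @return An object of class `"romt"`: per-pair velocity fields,
#'   interpolated densities, energy/misfit breakdown and convergence history,
#'   with `print`, `summary`, `coef`, `fitted`, `residuals`, `simulate` and
#'   `plot` methods.
#' @export
romt <- function(x, mu_final = NULL, grid = NULL, sigma2 = 0.002, xi = 50,
                 n_steps = 10L, psi = 1, control = romt_control(),
                 verbose = FALSE) {
  if (inherits(x, "density_series")) {
    frames <- x$frames
    times <- x$times
    grid <- x$grid
  } else {
    if (is.null(mu_final)) stop("supply mu_final or a density_series")
    if (is.null(grid)) grid <- image_grid(dim(x))
    frames <- list(x, mu_final)
    times <- c(0, 1)
  }
  if (length(frames) < 2L) stop("need at least two frames")
  for (f in frames) check_scalar_field(f, grid, nonneg = TRUE, name = "frame")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (xi <= 0) stop("xi must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")

  sums <- vapply(frames, sum, numeric(1))
  if (max(abs(sums - sums[1])) > 1e-6 * max(sums[1], .Machine$double.eps)) {
    warning("frame intensity totals differ; consider normalize_total_intensity()")
  }

  n_pairs <- length(frames) - 1L
  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    if (verbose) message(sprintf("pair %d/%d", p, n_pairs))
    fit <- tryCatch(
      gauss_newton_pair(as.numeric(frames[[p]]),
                        as.numeric(frames[[p + 1L]]),
                        grid, sigma2, xi, psi, n_steps, control,
                        verbose = verbose),
      error = function(e) stop(sprintf("pair %d: %s", p, conditionMessage(e)),
                               call. = FALSE))
    fit$v <- array(fit$v, c(grid$dims, 3L, n_steps))
    fit$interpolants <- lapply(fit$mus, array, dim = grid$dims)
    fit$mus <- NULL
    if (fit$flag == "line_search_exhausted") {
      warning(sprintf("pair %d: line search exhausted; returning best iterate", p))
    }
    pairs[[p]] <- fit
  }
  structure(list(pairs = pairs, grid = grid, frames = frames, times = times,
                 sigma2 = sigma2, xi = xi, psi = psi, n_steps = n_steps,
                 dt = 1 / n_steps, control = control, call = match.call()),
            class = "romt")
}

#' Mass-weighted mean advective speed of a fitted model
#'
#' The density-weighted average of `|v|` over all cells and solver steps:
#' `sum mu_{n-1} |v_n| / sum mu_{n-1}`, in world length per normalized pair
#' interval. Used e.g. to compare solves at different diffusivities on a
#' pure-diffusion phantom, where forcing advection inflates this number.
#'
#' @param fit an `"romt"` object.
#' @return Scalar speed.
#' @export
mean_advective_speed <- function(fit) {
  stopifnot(inherits(fit, "romt"))
  num <- 0; den <- 0
  for (pair in fit$pairs) {
    for (n in seq_len(fit$n_steps)) {
      mu <- as.numeric(pair$interpolants[[n]])
      sp <- sqrt(rowSums(matrix(pair$v[, , , , n], ncol = 3L)^2))
      num <- num + sum(mu * sp)
      den <- den + sum(mu)
    }
  }
  num / den
}
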