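#' Oriented boundary between two compartment masks
#'
#' Collects every 6-connected pair of adjacent cells with one cell in
#' `mask_from` and one in `mask_to` as an oriented face: source cell, target
#' cell, outward unit normal (axis-aligned, pointing from source into
#' target) and face area `dx^2`.
#'
#' @param mask_from,mask_to disjoint logical arrays on the same grid.
#' @param grid an `image_grid`.
#' @return An object of class `"compartment_boundary"`: a data frame of
#'   faces (`from`, `to` linear cell indices, `axis`, `sign`) plus the grid.
#' @export
extract_boundary <- function(mask_from, mask_to, grid) {
  stopifnot(is.array(mask_from), is.array(mask_to))
  if (!identical(dim(mask_from), as.integer(grid$dims)) ||
      !identical(dim(mask_to), as.integer(grid$dims))) {
    stop("masks must match the grid dims")
  }
  if (any(mask_from & mask_to)) stop("masks overlap")
  m <- grid$dims
  faces <- list()
  lin <- array(seq_len(grid$n_cells), m)
  for (a in 1:3) {
    if (m[a] == 1L) next
    idx_lo <- seq_len(m[a] - 1L)
    f_lo <- index_axis(mask_from, a, idx_lo)
    f_hi <- index_axis(mask_from, a, idx_lo + 1L)
    t_lo <- index_axis(mask_to, a, idx_lo)
    t_hi <- index_axis(mask_to, a, idx_lo + 1L)
    l_lo <- index_axis(lin, a, idx_lo)
    l_hi <- index_axis(lin, a, idx_lo + 1L)
    up <- which(f_lo & t_hi)     # normal along +axis
    dn <- which(f_hi & t_lo)     # normal along -axis
    if (length(up)) {
      faces[[length(faces) + 1L]] <- data.frame(from = l_lo[up], to = l_hi[up],
                                                axis = a, sign = 1L)
    }
    if (length(dn)) {
      faces[[length(faces) + 1L]] <- data.frame(from = l_hi[dn], to = l_lo[dn],
                                                axis = a, sign = -1L)
    }
  }
  faces <- if (length(faces)) do.call(rbind, faces) else
    data.frame(from = integer(0), to = integer(0), axis = integer(0),
               sign = integer(0))
  structure(list(faces = faces, grid = grid), class = "compartment_boundary")
}

#' @export
print.compartment_boundary <- function(x, ...) {
  cat(sprintf("<compartment_boundary> %d faces, face area %g\n",
              nrow(x$faces), x$grid$dx^2))
  invisible(x)
}

#' Advective and diffusive flux across a compartment boundary
#'
#' Evaluates the total flux `j_AD = -(D grad(mu) - mu v)` through each
#' oriented face: per face, `j_AD . n * dx^2`, positive when mass moves from
#' the source into the target compartment. Density and velocity are
#' interpolated to the face by the arithmetic mean of the two adjacent
#' cells; the normal density gradient uses the two-point difference.
#'
#' @param mu scalar field.
#' @param v vector field.
#' @param sigma2 diffusivity.
#' @param boundary a `"compartment_boundary"`.
#' @return Data frame with per-face `advective`, `diffusive` and `total`
#'   flux (mass per unit time).
#' @export
total_flux <- function(mu, v, sigma2, boundary) {
  stopifnot(inherits(boundary, "compartment_boundary"))
  grid <- boundary$grid
  check_scalar_field(mu, grid)
  check_vector_field(v, grid)
  fc <- boundary$faces
  if (nrow(fc) == 0L) {
    return(data.frame(advective = numeric(0), diffusive = numeric(0),
                      total = numeric(0)))
  }
  muv <- as.numeric(mu)
  vm <- matrix(v, nrow = grid$n_cells, ncol = 3L)
  area <- grid$dx^2
  mu_face <- 0.5 * (muv[fc$from] + muv[fc$to])
  vn_face <- 0.5 * (vm[cbind(fc$from, fc$axis)] + vm[cbind(fc$to, fc$axis)]) *
    fc$sign
  dmu_dn <- (muv[fc$to] - muv[fc$from]) / grid$dx
  adv <- mu_face * vn_face * area
  dif <- -sigma2 * dmu_dn * area
  data.frame(advective = adv, diffusive = dif, total = adv + dif)
}

#' Net directed mass influx over a fitted timeline
#'
#' Integrates the boundary flux over every solver step of a fitted rOMT
#' model, keeping only the positive (source-into-target) face fluxes: the
#' cumulative net mass transferred, e.g. from the CSF into the tissue
#' compartment. Density is evaluated mid-interval
#' (`(mu_{n-1} + mu_n) / 2`) with the step's velocity.
#'
#' @param fit an `"romt"` object.
#' @param boundary a `"compartment_boundary"` on the fit's grid.
#' @param signed if TRUE, sum all face fluxes (signed net transfer) instead
#'   of only the positive ones.
#' @return List with `total` (cumulative influx) and `curve` (per-step data
#'   frame `time`, `influx`).
#' @export
net_directed_influx <- function(fit, boundary, signed = FALSE) {
  stopifnot(inherits(fit, "romt"), inherits(boundary, "compartment_boundary"))
  N <- fit$n_steps
  dt <- fit$dt
  times <- numeric(0)
  rate <- numeric(0)
  for (p in seq_along(fit$pairs)) {
    pair <- fit$pairs[[p]]
    for (n in seq_len(N)) {
      mu_mid <- 0.5 * (pair$interpolants[[n]] + pair$interpolants[[n + 1L]])
      vn <- array(pair$v[, , , , n], c(fit$grid$dims, 3L))
      fx <- total_flux(mu_mid, vn, fit$sigma2, boundary)$total
      val <- if (signed) sum(fx) else sum(fx[fx > 0])
      times <- c(times, (p - 1) + n * dt)
      rate <- c(rate, val)
    }
  }
  list(total = sum(rate) * dt,
       curve = data.frame(time = times, influx = rate * dt))
}

#' Flux of a simulated series across a boundary
#'
#' The same face-flux integration for a forward-simulated series with a
#' known constant velocity field: per frame interval, flux is accumulated at
#' the inter-frame midpoint densities. Used for divergence-theorem
#' consistency checks against compartment mass changes.
#'
#' @param series a `density_series`.
#' @param v constant vector field (NULL for pure diffusion).
#' @param sigma2 diffusivity used in the simulation.
#' @param boundary a `"compartment_boundary"`.
#' @param signed sum all face fluxes instead of only positive ones.
#' @return List with `total` and per-interval `curve`.
#' @export
series_influx <- function(series, v, sigma2, boundary, signed = FALSE) {
  stopifnot(inherits(series, "density_series"))
  grid <- series$grid
  if (is.null(v)) v <- zero_vector_field(grid)
  nf <- length(series$frames)
  times <- numeric(0); vals <- numeric(0)
  for (k in seq_len(nf - 1L)) {
    dt <- series$times[k + 1L] - series$times[k]
    mu_mid <- 0.5 * (series$frames[[k]] + series$frames[[k + 1L]])
    fx <- total_flux(mu_mid, v, sigma2, boundary)$total
    val <- if (signed) sum(fx) else sum(fx[fx > 0])
    times <- c(times, series$times[k + 1L])
    vals <- c(vals, val * dt)
  }
  list(total = sum(vals), curve = data.frame(time = times, influx = vals))
}
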