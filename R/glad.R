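#' Augmented velocity field
#'
#' The effective velocity of the conservation form of the advection-diffusion
#' constraint: `v_aug = v - sigma2 * grad(log mu)`. Pathlines integrate this
#' field, so diffusion contributes gradient-driven drift to particle
#' trajectories. The density is floored at `floor_frac * max(mu)` before the
#' log gradient to keep the field finite in empty regions.
#'
#' @param v cell-centered vector field.
#' @param mu nonnegative scalar field.
#' @param grid an `image_grid`.
#' @param sigma2 diffusivity.
#' @param floor_frac relative density floor.
#' @return Vector field of dim `c(grid$dims, 3)`.
#' @export
augmented_velocity <- function(v, mu, grid, sigma2, floor_frac = 1e-4) {
  check_vector_field(v, grid)
  check_scalar_field(mu, grid, nonneg = TRUE)
  if (sigma2 == 0 || max(mu) == 0) return(v)
  lmu <- log(pmax(mu, floor_frac * max(mu)))
  v - sigma2 * gradient_field(array(lmu, grid$dims), grid)
}

#' Select pathline start points by signal increase
#'
#' Returns the voxels whose percent-of-baseline signal rises by at least
#' `threshold` (fraction, default 0.12 = 12%) over the series, optionally
#' decimated by a per-axis stride. By default a voxel qualifies if its
#' maximum increase over the interval reaches the threshold; `rule =
#' "all_frames"` requires every post-baseline frame to stay above it.
#'
#' @param series a `density_series` in percent-baseline units.
#' @param threshold minimum fractional increase over baseline.
#' @param stride keep every `stride`-th voxel along each axis.
#' @param rule `"max"` (default) or `"all_frames"`.
#' @return Integer matrix of seed voxel coordinates (one row per seed), with
#'   the linear indices as attribute `"index"`.
#' @export
select_start_points <- function(series, threshold = 0.12, stride = 1L,
                                rule = c("max", "all_frames")) {
  stopifnot(inherits(series, "density_series"))
  rule <- match.arg(rule)
  if (series$units != "percent_baseline") {
    stop("series must be in percent-baseline units (see percent_baseline())")
  }
  inc <- lapply(series$frames, function(f) f / 100 - 1)
  agg <- if (rule == "max") Reduce(pmax, inc) else Reduce(pmin, inc)
  sel <- agg >= threshold
  if (stride > 1L) {
    m <- series$grid$dims
    keep1 <- (seq_len(m[1]) - 1L) %% stride == 0L
    keep2 <- (seq_len(m[2]) - 1L) %% stride == 0L
    keep3 <- (seq_len(m[3]) - 1L) %% stride == 0L
    sel <- sel & outer(outer(keep1, keep2, "&"), keep3, "&")
  }
  idx <- which(sel)
  if (length(idx) == 0L) warning("no voxels pass the start-point threshold")
  out <- arrayInd(idx, series$grid$dims)
  attr(out, "index") <- idx
  out
}

# Normalize seed input to a matrix of voxel coordinates.
as_seed_matrix <- function(seeds, grid) {
  if (is.logical(seeds) && is.array(seeds)) seeds <- which(seeds)
  if (is.null(dim(seeds))) {
    if (length(seeds) == 3L && !is.integer(seeds)) seeds <- matrix(seeds, 1L)
    else seeds <- arrayInd(as.integer(seeds), grid$dims)
  }
  seeds <- matrix(as.numeric(seeds), ncol = 3L)
  if (any(seeds < 0.5) || any(sweep(seeds, 2, grid$dims + 0.5) > 0)) {
    stop("seeds outside the grid domain")
  }
  seeds
}

# RK4 integration of seeds through a sequence of frozen fields, each active
# for its duration. Positions evolve in voxel coordinates
# (dx/dt = v_world / dx); speed is |v| in world units. Trajectories leaving
# the domain are truncated.
integrate_core <- function(fields, durations, grid, seeds, step_dt) {
  ns <- nrow(seeds)
  substeps <- pmax(1L, as.integer(round(durations / step_dt)))
  n_samples <- sum(substeps) + 1L
  pts <- array(NA_real_, c(ns, n_samples, 3L))
  spd <- matrix(NA_real_, ns, n_samples)
  pos <- seeds
  active <- rep(TRUE, ns)
  eval_v <- function(f, p) interp_field(f, grid, p)
  sample_i <- 1L
  pts[, 1L, ] <- pos
  spd[, 1L] <- sqrt(rowSums(eval_v(fields[[1L]], pos)^2))
  lo <- 0.5; hi <- grid$dims + 0.5
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    h <- durations[k] / substeps[k]
    for (s in seq_len(substeps[k])) {
      sample_i <- sample_i + 1L
      if (any(active)) {
        p <- pos[active, , drop = FALSE]
        k1 <- eval_v(f, p) / grid$dx
        k2 <- eval_v(f, p + 0.5 * h * k1) / grid$dx
        k3 <- eval_v(f, p + 0.5 * h * k2) / grid$dx
        k4 <- eval_v(f, p + h * k3) / grid$dx
        pnew <- p + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
        inside <- pnew[, 1] >= lo & pnew[, 1] <= hi[1] &
          pnew[, 2] >= lo & pnew[, 2] <= hi[2] &
          pnew[, 3] >= lo & pnew[, 3] <= hi[3]
        act_idx <- which(active)
        pos[act_idx[inside], ] <- pnew[inside, , drop = FALSE]
        active[act_idx[!inside]] <- FALSE
        still <- act_idx[inside]
        if (length(still)) {
          pts[still, sample_i, ] <- pos[still, , drop = FALSE]
          spd[still, sample_i] <- sqrt(rowSums(
            eval_v(f, pos[still, , drop = FALSE])^2))
        }
      }
    }
  }
  list(points = pts, speeds = spd)
}

make_pathline_set <- function(res, seeds, grid, provenance = list()) {
  ns <- nrow(seeds)
  pls <- vector("list", ns)
  for (i in seq_len(ns)) {
    keep <- which(!is.na(res$speeds[i, ]))
    pv <- matrix(res$points[i, keep, ], ncol = 3L)
    pls[[i]] <- list(points = voxel_to_world(grid, pv),
                     voxel_points = pv,
                     speeds = res$speeds[i, keep],
                     start = seeds[i, ],
                     cluster = NA_integer_)
  }
  structure(list(pathlines = pls, grid = grid, provenance = provenance),
            class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  npts <- vapply(x$pathlines, function(p) nrow(p$points), integer(1))
  ncl <- length(unique(stats::na.omit(vapply(x$pathlines, `[[`, integer(1), "cluster"))))
  cat(sprintf("<pathline_set> %d pathlines (%d-%d points each)%s\n",
              length(x$pathlines), if (length(npts)) min(npts) else 0L,
              if (length(npts)) max(npts) else 0L,
              if (ncl > 0) sprintf(", %d clusters", ncl) else ""))
  invisible(x)
}

#' @export
length.pathline_set <- function(x) length(x$pathlines)

#' Integrate pathlines through a fitted rOMT timeline
#'
#' Integrates each seed forward through the piecewise-in-time augmented
#' velocity field of a fitted model with 4th-order Runge-Kutta and trilinear
#' spatial interpolation, recording position and speed (the speedline) at
#' every step. Within solver step `n` of a pair the field is
#' `v_n - sigma2 * grad(log mu_{n-1})`, frozen over the step. Trajectories
#' leaving the domain are truncated at the boundary.
#'
#' @param fit an `"romt"` object.
#' @param seeds seed voxels: an n x 3 matrix of voxel coordinates, a vector
#'   of linear indices, or a logical array.
#' @param step_dt integration step in normalized pair time (each pair spans
#'   1 unit); defaults to a quarter of the solver step.
#' @param use_augmented use the augmented velocity (default) or the bare
#'   advective velocity, the two readings of "transport vector" speed.
#' @param floor_frac density floor for the log-gradient (see
#'   [augmented_velocity()]).
#' @return A `"pathline_set"`.
#' @export
integrate_pathlines <- function(fit, seeds, step_dt = NULL,
                                use_augmented = TRUE, floor_frac = 1e-4) {
  stopifnot(inherits(fit, "romt"))
  grid <- fit$grid
  seeds <- as_seed_matrix(seeds, grid)
  N <- fit$n_steps
  if (is.null(step_dt)) step_dt <- 1 / (4 * N)
  fields <- list()
  for (pair in fit$pairs) {
    for (n in seq_len(N)) {
      vn <- array(pair$v[, , , , n], c(grid$dims, 3L))
      if (use_augmented) {
        vn <- augmented_velocity(vn, pair$interpolants[[n]], grid,
                                 fit$sigma2, floor_frac)
      }
      fields[[length(fields) + 1L]] <- vn
    }
  }
  res <- integrate_core(fields, rep(1 / N, length(fields)), grid, seeds, step_dt)
  make_pathline_set(res, seeds, grid,
                    provenance = list(step_dt = step_dt,
                                      use_augmented = use_augmented,
                                      sigma2 = fit$sigma2))
}

#' Streamlines of a frozen velocity field
#'
#' Integrates curves tangent to a single-time velocity field (the Eulerian
#' snapshot view), with the same RK4 integrator and speed recording as
#' [integrate_pathlines()]. Used e.g. for diffusivity-sweep comparisons of
#' flow-field smoothness.
#'
#' @param v vector field at one time step.
#' @param grid an `image_grid`.
#' @param seeds seed voxels (see [integrate_pathlines()]).
#' @param total_time integration span.
#' @param step_dt RK4 step.
#' @return A `"pathline_set"` of streamlines.
#' @export
compute_streamlines <- function(v, grid, seeds, total_time = 1,
                                step_dt = total_time / 100) {
  check_vector_field(v, grid)
  seeds <- as_seed_matrix(seeds, grid)
  res <- integrate_core(list(v), total_time, grid, seeds, step_dt)
  make_pathline_set(res, seeds, grid, provenance = list(step_dt = step_dt))
}

# Resample a polyline to n points equally spaced in arc length.
resample_polyline <- function(pts, n = 12L) {
  if (nrow(pts) == 1L) return(pts[rep(1L, n), , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[rep(1L, n), , drop = FALSE])
  keep <- c(TRUE, seg > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  target <- seq(0, total, length.out = n)
  out <- matrix(0, n, 3L)
  for (c in 1:3) out[, c] <- stats::approx(s, pts[, c], xout = target)$y
  out
}

#' Mean direct-flip distance between two resampled curves
#'
#' The QuickBundles metric: the mean pointwise Euclidean distance between two
#' curves with the same number of points, minimized over reversing one of
#' them. Symmetric, nonnegative, flip-invariant and zero on identical curves.
#'
#' @param a,b matrices of curve points (same number of rows).
#' @return Scalar distance.
#' @export
mdf_distance <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("curves must have the same number of points")
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' Cluster pathlines and remove insignificant clusters
#'
#' QuickBundles-style single-pass clustering: each pathline (resampled to
#' `n_points` equispaced points) is assigned to the nearest cluster centroid
#' under the mean direct-flip distance if within `cluster_threshold`, else it
#' founds a new cluster; centroids are updated incrementally with flip
#' alignment. Clusters with fewer than `min_cluster_size` members are then
#' removed, and surviving pathlines carry their cluster label.
#'
#' @param pset a `"pathline_set"`.
#' @param cluster_threshold assignment distance, world units (default 2
#'   voxel lengths).
#' @param min_cluster_size minimum surviving cluster size.
#' @param n_points resampling count for the metric.
#' @return The filtered, labeled `"pathline_set"`; cluster sizes in
#'   attribute `"cluster_sizes"`.
#' @export
cluster_and_filter <- function(pset, cluster_threshold = 2 * pset$grid$dx,
                               min_cluster_size = 5L, n_points = 12L) {
  stopifnot(inherits(pset, "pathline_set"))
  np <- length(pset$pathlines)
  if (np == 0L) return(pset)
  rs <- lapply(pset$pathlines, function(p) resample_polyline(p$points, n_points))
  centroids <- list()
  counts <- integer(0)
  labels <- integer(np)
  for (i in seq_len(np)) {
    cur <- rs[[i]]
    best <- Inf; best_k <- 0L; best_flip <- FALSE
    for (k in seq_along(centroids)) {
      cen <- centroids[[k]] / counts[k]
      direct <- mean(sqrt(rowSums((cur - cen)^2)))
      flip <- mean(sqrt(rowSums((cur[n_points:1, , drop = FALSE] - cen)^2)))
      d <- min(direct, flip)
      if (d < best) { best <- d; best_k <- k; best_flip <- flip < direct }
    }
    if (best <= cluster_threshold) {
      add <- if (best_flip) cur[n_points:1, , drop = FALSE] else cur
      centroids[[best_k]] <- centroids[[best_k]] + add
      counts[best_k] <- counts[best_k] + 1L
      labels[i] <- best_k
    } else {
      centroids[[length(centroids) + 1L]] <- cur
      counts <- c(counts, 1L)
      labels[i] <- length(centroids)
    }
  }
  keep_cluster <- which(counts >= min_cluster_size)
  keep <- labels %in% keep_cluster
  out <- pset
  out$pathlines <- pset$pathlines[keep]
  relabel <- match(labels[keep], keep_cluster)
  for (i in seq_along(out$pathlines)) out$pathlines[[i]]$cluster <- relabel[i]
  attr(out, "cluster_sizes") <- counts[keep_cluster]
  attr(out, "n_clusters_total") <- length(counts)
  out
}

#' Rasterize pathlines back to the voxel grid
#'
#' Deposits every pathline sample to neighboring cell centers by trilinear
#' weights. `mode = "binary"` returns the 0/1 mask of the pathline network;
#' `mode = "speed"` returns the deposition-weighted average speed per voxel.
#'
#' @param pset a (filtered) `"pathline_set"`.
#' @param mode `"binary"` or `"speed"`.
#' @return Scalar field on the set's grid.
#' @export
rasterize_pathlines <- function(pset, mode = c("binary", "speed")) {
  stopifnot(inherits(pset, "pathline_set"))
  mode <- match.arg(mode)
  grid <- pset$grid
  m <- grid$dims
  M <- grid$n_cells
  wsum <- numeric(M)
  ssum <- numeric(M)
  for (p in pset$pathlines) {
    pts <- p$voxel_points
    if (is.null(pts)) pts <- world_to_voxel(grid, p$points)
    n <- nrow(pts)
    lo <- matrix(1, n, 3); hi <- matrix(m, n, 3, byrow = TRUE)
    pp <- pmin(pmax(pts, lo), hi)
    i0 <- matrix(0L, n, 3); fr <- matrix(0, n, 3)
    for (c in 1:3) {
      if (m[c] == 1L) { i0[, c] <- 1L; fr[, c] <- 0 }
      else { i0[, c] <- pmin(floor(pp[, c]), m[c] - 1L); fr[, c] <- pp[, c] - i0[, c] }
    }
    for (b3 in 0:1) for (b2 in 0:1) for (b1 in 0:1) {
      w <- (if (b1 == 1L) fr[, 1] else 1 - fr[, 1]) *
        (if (b2 == 1L) fr[, 2] else 1 - fr[, 2]) *
        (if (b3 == 1L) fr[, 3] else 1 - fr[, 3])
      j <- pmin(i0[, 1] + b1, m[1]) +
        (pmin(i0[, 2] + b2, m[2]) - 1L) * m[1] +
        (pmin(i0[, 3] + b3, m[3]) - 1L) * m[1] * m[2]
      nz <- w > 0
      if (any(nz)) {
        acc <- rowsum(cbind(w[nz], w[nz] * p$speeds[nz]), group = j[nz])
        ids <- as.integer(rownames(acc))
        wsum[ids] <- wsum[ids] + acc[, 1]
        ssum[ids] <- ssum[ids] + acc[, 2]
      }
    }
  }
  if (mode == "binary") {
    array(as.numeric(wsum > 1e-12), m)
  } else {
    out <- numeric(M)
    nz <- wsum > 1e-12
    out[nz] <- ssum[nz] / wsum[nz]
    array(out, m)
  }
}

#' Per-mask pathline volume and mean speed
#'
#' For each mask: the pathline volume (count of binary-map voxels inside the
#' mask, a proxy for total flux of moving solute) and the mean of the speed
#' map over those voxels (`NA` when the mask misses the network).
#'
#' @param binary_map binary pathline-network field
#'   (see [rasterize_pathlines()]).
#' @param speed_map speed field on the same grid.
#' @param masks named list of logical arrays.
#' @return A data frame with columns `mask`, `pathline_volume`,
#'   `mean_speed`.
#' @export
summarize_by_mask <- function(binary_map, speed_map, masks) {
  if (!is.list(masks)) masks <- list(mask = masks)
  if (is.null(names(masks))) names(masks) <- paste0("mask", seq_along(masks))
  net <- binary_map > 0
  rows <- lapply(names(masks), function(nm) {
    sel <- net & masks[[nm]]
    data.frame(mask = nm, pathline_volume = sum(sel),
               mean_speed = if (any(sel)) mean(speed_map[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}
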