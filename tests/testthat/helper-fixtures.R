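# Shared small fixtures; everything is generated in code.

line_grid <- function(n) image_grid(c(n, 1L, 1L))

line_field <- function(vals) array(vals, c(length(vals), 1L, 1L))

random_density <- function(grid, seed = 1, offset = 0) {
  set.seed(seed)
  array(stats::runif(grid$n_cells) + offset, grid$dims)
}

random_velocity <- function(grid, seed = 1, sd = 0.3) {
  set.seed(seed)
  array(stats::rnorm(3 * grid$n_cells, sd = sd), c(grid$dims, 3L))
}

# Independent brute-force gradient oracle: explicit stencil loops.
stencil_gradient <- function(f, dx) {
  d <- dim(f)
  out <- array(0, c(d, 3L))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (d[1] > 1) {
      ip <- min(i + 1, d[1]); im <- max(i - 1, 1)
      out[i, j, k, 1] <- (f[ip, j, k] - f[im, j, k]) / ((ip - im) * dx)
    }
    if (d[2] > 1) {
      jp <- min(j + 1, d[2]); jm <- max(j - 1, 1)
      out[i, j, k, 2] <- (f[i, jp, k] - f[i, jm, k]) / ((jp - jm) * dx)
    }
    if (d[3] > 1) {
      kp <- min(k + 1, d[3]); km <- max(k - 1, 1)
      out[i, j, k, 3] <- (f[i, j, kp] - f[i, j, km]) / ((kp - km) * dx)
    }
  }
  out
}

# Straight pathline through given voxel centers, constant speed.
straight_pathline_set <- function(grid, centers, speed = 1) {
  pts <- matrix(as.numeric(centers), ncol = 3)
  structure(list(
    pathlines = list(list(points = voxel_to_world(grid, pts),
                          voxel_points = pts,
                          speeds = rep(speed, nrow(pts)),
                          start = pts[1, ], cluster = NA_integer_)),
    grid = grid, provenance = list()), class = "pathline_set")
}
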