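test_that("augmented velocity reduces to v for sigma2 = 0 or constant density", {
  g <- image_grid(c(6, 6, 6))
  v <- random_velocity(g, seed = 1)
  mu <- random_density(g, seed = 2, offset = 0.5)
  expect_identical(augmented_velocity(v, mu, g, 0), v)
  expect_equal(augmented_velocity(v, array(3, g$dims), g, 0.01), v,
               tolerance = 1e-12)
})

test_that("augmented velocity matches the analytic log-Gaussian gradient", {
  # 1D Gaussian mu ~ exp(-x^2 / 2 s^2), v = 0: v_aug = sigma2 * x / s^2
  g <- image_grid(c(41, 1, 1))
  x <- seq_len(41) - 21
  s <- 4
  mu <- array(exp(-0.5 * x^2 / s^2), c(41, 1, 1))
  va <- augmented_velocity(constant_field(g, c(0, 0, 0)), mu, g,
                           sigma2 = 0.002, floor_frac = 1e-12)
  interior <- 10:32  # away from the floor region and boundary stencils
  expect_equal(va[interior, 1, 1, 1], 0.002 * x[interior] / s^2,
               tolerance = 1e-3)
})

test_that("start points follow the percent-increase rule", {
  g <- image_grid(c(4, 4, 1))
  f1 <- array(100, g$dims)
  f2 <- array(100, g$dims)
  f2[2, 2, 1] <- 115   # +15% passes
  f2[3, 3, 1] <- 110   # +10% fails at the 12% threshold
  ser <- density_series(list(f1, f2), grid = g, units = "raw")
  ser$units <- "percent_baseline"
  seeds <- select_start_points(ser, threshold = 0.12)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds[1, ], c(2L, 2L, 1L), ignore_attr = TRUE)
  # constant series selects nothing
  cser <- density_series(list(f1, f1), grid = g)
  cser$units <- "percent_baseline"
  expect_warning(s0 <- select_start_points(cser), "no voxels")
  expect_equal(nrow(s0), 0L)
  expect_error(select_start_points(density_series(list(f1, f2), grid = g)),
               "percent-baseline")
})

test_that("pathline integration of zero and constant fields is exact", {
  g <- image_grid(c(12, 12, 12))
  seeds <- matrix(c(6, 6, 6), 1)
  zero <- compute_streamlines(constant_field(g, c(0, 0, 0)), g, seeds,
                              total_time = 1, step_dt = 0.1)
  p <- zero$pathlines[[1]]
  expect_true(all(abs(sweep(p$points, 2, p$points[1, ])) < 1e-14))
  expect_equal(p$speeds, rep(0, nrow(p$points)))

  u <- c(0.3, 0.2, -0.1)
  cf <- compute_streamlines(constant_field(g, u), g, seeds,
                            total_time = 2, step_dt = 0.1)
  p <- cf$pathlines[[1]]
  disp <- p$points[nrow(p$points), ] - p$points[1, ]
  expect_equal(as.numeric(disp), u * 2, tolerance = 1e-10)
  expect_equal(p$speeds, rep(sqrt(sum(u^2)), nrow(p$points)),
               tolerance = 1e-12)
})

test_that("RK4 closes a rotation orbit and converges at 4th order", {
  g <- image_grid(c(21, 21, 21))
  v <- rotation_field(g, center = c(11, 11, 11), omega = 1)
  seed <- matrix(c(15, 11, 11), 1)  # radius 4, well inside the domain
  TT <- 2 * pi
  err_at <- function(h) {
    s <- compute_streamlines(v, g, seed, total_time = TT, step_dt = h)
    p <- s$pathlines[[1]]$points
    sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }
  e1 <- err_at(TT / 64)
  expect_lt(e1, 1e-3)
  e2 <- err_at(TT / 128)
  expect_gt(e1 / e2, 12)   # ~16x per halving for a 4th-order scheme
  expect_lt(e1 / e2, 20)
})

test_that("MDF distance is symmetric, flip-invariant, exact for offset lines", {
  a <- cbind(seq(0, 1, length.out = 12), 0, 0)
  b <- sweep(a, 2, c(0, 0.7, 0))  # parallel offset by |d| = 0.7
  expect_equal(mdf_distance(a, b), 0.7)
  expect_equal(mdf_distance(b, a), 0.7)
  expect_equal(mdf_distance(a, a), 0)
  expect_equal(mdf_distance(a, b[12:1, ]), 0.7)  # flip invariance
  set.seed(3)
  c1 <- matrix(rnorm(36), 12, 3); c2 <- matrix(rnorm(36), 12, 3)
  expect_gte(mdf_distance(c1, c2), 0)
  expect_equal(mdf_distance(c1, c2), mdf_distance(c2, c1))
  expect_equal(mdf_distance(c1, c2), mdf_distance(c1, c2[12:1, ]))
})

test_that("clustering groups by threshold and removes small clusters", {
  g <- image_grid(c(20, 20, 20))
  mk <- function(y) {
    pts <- cbind(seq(2, 18, length.out = 10), y, 10)
    list(points = pts, voxel_points = pts, speeds = rep(1, 10),
         start = pts[1, ], cluster = NA_integer_)
  }
  # two identical pathlines cluster together whatever the threshold
  ps <- structure(list(pathlines = list(mk(5), mk(5)), grid = g,
                       provenance = list()), class = "pathline_set")
  out <- cluster_and_filter(ps, cluster_threshold = 0.1, min_cluster_size = 2)
  expect_length(out$pathlines, 2)
  expect_equal(unique(vapply(out$pathlines, `[[`, integer(1), "cluster")), 1L)

  # offset 3 > threshold 2: separate clusters; singletons removed at size 2
  ps2 <- structure(list(pathlines = list(mk(5), mk(5), mk(8)), grid = g,
                        provenance = list()), class = "pathline_set")
  out2 <- cluster_and_filter(ps2, cluster_threshold = 2, min_cluster_size = 2)
  expect_length(out2$pathlines, 2)
  expect_equal(attr(out2, "n_clusters_total"), 2L)
  # offset 1 <= threshold 2: one cluster of three
  out3 <- cluster_and_filter(
    structure(list(pathlines = list(mk(5), mk(6), mk(5.5)), grid = g,
                   provenance = list()), class = "pathline_set"),
    cluster_threshold = 2, min_cluster_size = 3)
  expect_length(out3$pathlines, 3)
})

test_that("rasterization counts voxel-center pathline points exactly", {
  g <- image_grid(c(10, 10, 10))
  ps <- straight_pathline_set(g, cbind(2:6, 5, 5), speed = 0.8)
  bin <- rasterize_pathlines(ps, "binary")
  expect_equal(sum(bin), 5)
  spd <- rasterize_pathlines(ps, "speed")
  expect_equal(unique(spd[bin > 0]), 0.8)
  # empty set rasterizes to zero
  empty <- structure(list(pathlines = list(), grid = g, provenance = list()),
                     class = "pathline_set")
  expect_equal(sum(rasterize_pathlines(empty, "binary")), 0)
})

test_that("mask summaries partition the pathline network", {
  g <- image_grid(c(10, 10, 10))
  ps <- straight_pathline_set(g, cbind(2:9, 5, 5), speed = 1.5)
  bin <- rasterize_pathlines(ps, "binary")
  spd <- rasterize_pathlines(ps, "speed")
  left <- array(FALSE, g$dims); left[1:5, , ] <- TRUE
  right <- !left
  off <- array(FALSE, g$dims); off[, 9:10, ] <- TRUE
  s <- summarize_by_mask(bin, spd, list(left = left, right = right, off = off))
  expect_equal(s$pathline_volume[1] + s$pathline_volume[2], sum(bin))
  expect_equal(s$mean_speed[1], 1.5)
  expect_equal(s$pathline_volume[3], 0L, ignore_attr = TRUE)
  expect_true(is.na(s$mean_speed[3]))
  whole <- summarize_by_mask(bin, spd, list(all = array(TRUE, g$dims)))
  expect_equal(whole$pathline_volume, sum(bin))
})
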