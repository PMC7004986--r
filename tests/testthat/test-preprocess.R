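test_that("percent-baseline conversion is voxelwise and keeps baselines", {
  g <- image_grid(c(3, 3, 1))
  base <- array(200, g$dims)
  post <- array(230, g$dims)
  ser <- density_series(list(base, base, post), grid = g, baseline_count = 2)
  pct <- percent_baseline(ser)
  expect_equal(pct$frames[[1]], array(100, g$dims))
  expect_equal(pct$frames[[3]], array(115, g$dims))
  expect_equal(pct$units, "percent_baseline")
  expect_length(pct$frames, 3)

  # zero-baseline voxels are zeroed and counted
  base2 <- base; base2[1, 1, 1] <- 0
  ser2 <- density_series(list(base2, base2, post), grid = g, baseline_count = 2)
  pct2 <- percent_baseline(ser2)
  expect_equal(pct2$frames[[3]][1, 1, 1], 0)
  expect_equal(attr(pct2, "n_zero_baseline"), 1L)
})

test_that("total-intensity normalization equalizes frame sums", {
  g <- image_grid(c(2, 2, 1))
  f1 <- array(c(1, 2, 3, 4), g$dims)   # sum 10
  f2 <- 2 * f1                          # sum 20
  ser <- density_series(list(f1, f2), grid = g)
  nrm <- normalize_total_intensity(ser)
  expect_equal(attr(nrm, "scale_factors"), c(1, 0.5))
  expect_equal(nrm$frames[[2]], f1)
  # already equal sums: identity
  nrm2 <- normalize_total_intensity(density_series(list(f1, f1), grid = g))
  expect_equal(nrm2$frames[[2]], f1)
  expect_error(normalize_total_intensity(
    density_series(list(f1, array(0, g$dims)), grid = g)), "nonpositive")
})

test_that("percent-baseline + normalization is invariant to global rescaling", {
  g <- image_grid(c(4, 4, 4))
  set.seed(7)
  frames <- replicate(4, array(runif(g$n_cells, 50, 150), g$dims),
                      simplify = FALSE)
  ser <- density_series(frames, grid = g, baseline_count = 1)
  ser_scaled <- density_series(lapply(frames, `*`, 3.7), grid = g,
                               baseline_count = 1)
  out1 <- normalize_total_intensity(percent_baseline(ser))
  out2 <- normalize_total_intensity(percent_baseline(ser_scaled))
  for (k in seq_along(frames)) {
    expect_equal(out1$frames[[k]], out2$frames[[k]], tolerance = 1e-12)
  }
})

test_that("Gaussian smoothing conserves mass and matches the moment oracle", {
  g <- image_grid(c(21, 21, 21))
  delta <- array(0, g$dims); delta[11, 11, 11] <- 1
  fwhm <- 2 * sqrt(2 * log(2)) * 2.0    # sd = 2 voxels
  sm <- gaussian_smooth(delta, fwhm, grid = g)
  expect_equal(sum(sm), 1, tolerance = 1e-8)
  mom <- field_moments(sm, g)
  expect_lt(max(abs(mom$variance - 4)) / 4, 0.02)
  # fwhm = 0 is the identity
  expect_identical(gaussian_smooth(delta, 0, grid = g), delta)
  # series form conserves each frame's sum
  ser <- density_series(list(delta, 2 * delta), grid = g)
  smser <- gaussian_smooth(ser, fwhm)
  expect_equal(vapply(smser$frames, sum, numeric(1)), c(1, 2),
               tolerance = 1e-8)
})

test_that("window cropping selects the peak-anchored frame range", {
  g <- image_grid(c(2, 2, 2))
  frames <- lapply(c(1, 2, 5, 4, 3, 2), function(a) array(a, g$dims))
  ser <- density_series(frames, times = seq(0, 25, by = 5), grid = g)
  # peak at frame 3 (t = 10); 10-minute window keeps frames 3..5
  win <- crop_to_window(ser, duration = 10)
  expect_equal(win$times, c(10, 15, 20))
  expect_equal(win$frames[[1]][1, 1, 1], 5)
  # zero duration selects a single frame; whole-span window is the identity
  expect_length(crop_to_window(ser, start_time = 5, duration = 0)$frames, 1)
  expect_length(crop_to_window(ser, start_time = 0, duration = 25)$frames, 6)
  expect_error(crop_to_window(ser, start_time = 40, duration = 5), "outside")
})
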