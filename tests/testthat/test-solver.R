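test_that("forward propagation reduces to identity / pure diffusion", {
  g <- image_grid(c(8, 8, 8))
  mu0 <- gaussian_blob(g, sd = 1.5)
  vz <- array(0, c(g$dims, 3L, 3L))
  mus <- forward_propagate(mu0, vz, g, sigma2 = 0)
  for (m in mus) expect_equal(m, mu0, tolerance = 1e-14)

  # with v = 0 the recursion is repeated implicit diffusion; mass constant
  mus <- forward_propagate(mu0, vz, g, sigma2 = 0.3)
  ref <- mu0
  for (n in 1:3) {
    ref <- implicit_diffuse(ref, g, 0.3, 1 / 3)
    expect_equal(mus[[n + 1]], ref, tolerance = 1e-10)
    expect_equal(sum(mus[[n + 1]]), sum(mu0), tolerance = 1e-10)
  }
})

test_that("constant velocity displaces the blob center by v per unit time", {
  g <- image_grid(c(16, 16, 16))
  mu0 <- gaussian_blob(g, center = c(6, 8, 8), sd = 2)
  N <- 4
  vk <- constant_field(g, c(2, 1, 0))
  v <- array(rep(vk, N), c(g$dims, 3L, N))
  mus <- forward_propagate(mu0, v, g, sigma2 = 0)
  ctr <- field_moments(mus[[N + 1]], g)$center
  expect_lt(max(abs(ctr - c(8, 9, 8))), 0.25)
})

test_that("transport energy is the discrete Benamou-Brenier action", {
  # single cell, dt = dx = 1: 0.5 * mu * |v|^2
  g <- line_grid(1)
  mu <- list(line_field(2), line_field(2))
  v <- array(c(1, 0, 0), c(1, 1, 1, 3, 1))
  expect_equal(transport_energy(mu, v, g, dt = 1), 1)
  # zero velocity costs nothing; doubling v quadruples the cost
  g2 <- image_grid(c(4, 4, 4))
  mus <- replicate(3, random_density(g2, seed = 5), simplify = FALSE)
  v2 <- array(rnorm(g2$n_cells * 6, sd = 0.3), c(g2$dims, 3, 2))
  expect_equal(transport_energy(mus, 0 * v2, g2), 0)
  e1 <- transport_energy(mus, v2, g2)
  expect_gt(e1, 0)
  expect_equal(transport_energy(mus, 2 * v2, g2) / e1, 4, tolerance = 1e-12)
  expect_error(transport_energy(list(-mus[[1]], mus[[2]], mus[[3]]), v2, g2),
               "nonnegative")
})

test_that("objective decomposes into energy plus weighted endpoint misfit", {
  g <- image_grid(c(5, 5, 5))
  mu0 <- random_density(g, seed = 3, offset = 0.1)
  v <- array(0, c(g$dims, 3, 2))
  ob <- romt_objective(v, mu0, mu0, g, sigma2 = 0, xi = 7)
  expect_equal(as.numeric(ob), 0)
  muf <- random_density(g, seed = 4, offset = 0.1)
  ob <- romt_objective(v, mu0, muf, g, sigma2 = 0, xi = 7)
  expect_equal(as.numeric(ob), 7 * g$n_cells * sum((mu0 - muf)^2))
  expect_equal(attr(ob, "energy"), 0)
})

test_that("adjoint gradient matches central finite differences", {
  g <- image_grid(c(6, 6, 6))
  set.seed(42)
  mu0 <- random_density(g, seed = 42, offset = 0.1)
  muf <- random_density(g, seed = 43, offset = 0.1)
  v <- array(rnorm(g$n_cells * 6, sd = 0.2), c(g$dims, 3, 2))
  ob <- romt_objective(v, mu0, muf, g, sigma2 = 0.01, xi = 5, gradient = TRUE)
  gr <- attr(ob, "gradient")
  for (k in 1:3) {
    u <- array(rnorm(length(v)), dim(v)); u <- u / sqrt(sum(u^2))
    h <- 1e-5
    fp <- as.numeric(romt_objective(v + h * u, mu0, muf, g, sigma2 = 0.01, xi = 5))
    fm <- as.numeric(romt_objective(v - h * u, mu0, muf, g, sigma2 = 0.01, xi = 5))
    fd <- (fp - fm) / (2 * h)
    expect_lt(abs(fd - sum(gr * u)) / abs(fd), 1e-4)
  }
})

test_that("identical endpoints yield the zero-transport optimum", {
  g <- image_grid(c(8, 8, 8))
  mu <- gaussian_blob(g, sd = 1.5)
  fit <- romt(mu, mu, sigma2 = 0, xi = 50, n_steps = 3)
  p <- fit$pairs[[1]]
  expect_lt(max(abs(p$v)), 1e-6)
  expect_lt(p$energy, 1e-10)
  expect_equal(p$interpolants[[1]], mu)
})

test_that("objective is non-increasing across accepted iterates and the fit is deterministic", {
  g <- image_grid(c(10, 10, 10))
  mu0 <- gaussian_blob(g, center = c(4.5, 5.5, 5.5), sd = 1.6)
  muf <- gaussian_blob(g, center = c(6.5, 5.5, 5.5), sd = 1.6)
  ctrl <- romt_control(max_iter = 6)
  fit1 <- romt(mu0, muf, sigma2 = 0.001, xi = 50, n_steps = 4, control = ctrl)
  # monotone within each continuation level (the objective changes weight
  # between levels)
  h <- fit1$pairs[[1]]$convergence
  for (lv in unique(h$level)) {
    d <- diff(h$objective[h$level == lv])
    if (length(d)) expect_lte(max(d), 0)
  }
  fit2 <- romt(mu0, muf, sigma2 = 0.001, xi = 50, n_steps = 4, control = ctrl)
  expect_identical(fit1$pairs[[1]]$v, fit2$pairs[[1]]$v)
  # interpolant mass is constant along the timeline
  mass <- vapply(fit1$pairs[[1]]$interpolants, sum, numeric(1))
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-8)
  # all interpolants nonnegative (structural property of the scheme)
  expect_true(all(vapply(fit1$pairs[[1]]$interpolants,
                         function(m) min(m) >= 0, logical(1))))
})

test_that("series fits keep per-pair bookkeeping and near-zero flow on static data", {
  g <- image_grid(c(8, 8, 8))
  mu <- gaussian_blob(g, sd = 1.5)
  ser <- density_series(list(mu, mu, mu), grid = g)
  fit <- romt(ser, sigma2 = 0, xi = 50, n_steps = 2)
  expect_length(fit$pairs, 2)
  expect_lt(max(abs(coef(fit))), 1e-6)
  expect_equal(dim(coef(fit))[5], 4L)
  s <- summary(fit)
  expect_s3_class(s$pairs, "data.frame")
  expect_equal(nrow(s$pairs), 2L)
  expect_lt(max(vapply(residuals(fit), function(r) max(abs(r)), numeric(1))),
            1e-8)

  # a 21-frame series yields 20 pair solutions on a monotone timeline
  g8 <- image_grid(c(8, 8, 8))
  mu8 <- gaussian_blob(g8, sd = 1.5)
  ser21 <- density_series(rep(list(mu8), 21), times = seq(0, 100, by = 5),
                          grid = g8)
  fit21 <- romt(ser21, sigma2 = 0, xi = 50, n_steps = 1)
  expect_length(fit21$pairs, 20)
  expect_true(all(diff(fit21$times) > 0))
})
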