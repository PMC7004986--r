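#' @export
print.romt <- function(x, ...) {
  np <- length(x$pairs)
  cat(sprintf("rOMT fit: %d image pair%s on a %d x %d x %d grid (dx = %g)\n",
              np, if (np > 1) "s" else "",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$dx))
  cat(sprintf("  sigma2 = %g, xi = %g, N = %d steps/pair\n",
              x$sigma2, x$xi, x$n_steps))
  obj <- vapply(x$pairs, `[[`, numeric(1), "objective")
  en <- vapply(x$pairs, `[[`, numeric(1), "energy")
  cat(sprintf("  objective %s (transport energy %s)\n",
              paste(signif(obj, 4), collapse = ", "),
              paste(signif(en, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.romt <- function(object, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$pairs), function(p) {
    f <- object$pairs[[p]]
    mass <- vapply(f$interpolants, sum, numeric(1))
    data.frame(pair = p, iterations = f$iterations, objective = f$objective,
               energy = f$energy, misfit = f$misfit,
               mass_drift = max(abs(mass - mass[1])) / max(mass[1], 1e-300),
               flag = f$flag)
  }))
  out <- list(pairs = tab, mean_speed = mean_advective_speed(object),
              sigma2 = object$sigma2, n_steps = object$n_steps)
  class(out) <- "summary.romt"
  out
}

#' @export
print.summary.romt <- function(x, ...) {
  cat("rOMT fit summary\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("mass-weighted mean advective speed: %.4g (per pair interval)\n",
              x$mean_speed))
  invisible(x)
}

#' Velocity fields of a fitted rOMT model
#'
#' @param object an `"romt"` fit.
#' @param ... unused.
#' @return Array of dim `c(dims, 3, N_total)` concatenating the per-step
#'   velocities of all pairs along the timeline.
#' @export
coef.romt <- function(object, ...) {
  N <- object$n_steps
  total <- N * length(object$pairs)
  out <- array(0, c(object$grid$dims, 3L, total))
  k <- 0L
  for (pair in object$pairs) for (n in seq_len(N)) {
    k <- k + 1L
    out[, , , , k] <- pair$v[, , , , n]
  }
  out
}

#' Interpolated densities of a fitted rOMT model
#'
#' @param object an `"romt"` fit.
#' @param ... unused.
#' @return List of scalar fields along the concatenated timeline; the first
#'   element of each pair is the observed earlier frame.
#' @export
fitted.romt <- function(object, ...) {
  out <- list(object$pairs[[1]]$interpolants[[1]])
  for (pair in object$pairs) out <- c(out, pair$interpolants[-1])
  out
}

#' Endpoint residual fields
#'
#' The free-endpoint misfit `mu_N - mu_final` for each pair: what the noise
#' model absorbed instead of forcing transport.
#'
#' @param object an `"romt"` fit.
#' @param ... unused.
#' @return List of residual fields, one per pair.
#' @export
residuals.romt <- function(object, ...) {
  lapply(seq_along(object$pairs), function(p) {
    object$pairs[[p]]$interpolants[[object$n_steps + 1L]] -
      object$frames[[p + 1L]]
  })
}

#' Re-simulate the observed series under the fitted velocities
#'
#' Propagates the first observed frame through the fitted velocity timeline
#' (the model's idea of the data), optionally adding i.i.d. Gaussian
#' observation noise to each frame endpoint.
#'
#' @param object an `"romt"` fit.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param noise_sd standard deviation of the added observation noise
#'   (0 = noise-free model frames).
#' @param ... unused.
#' @return A list of `nsim` lists of frames (frame endpoints per pair).
#' @export
simulate.romt <- function(object, nsim = 1, seed = NULL, noise_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  endpoints <- lapply(object$pairs,
                      function(p) p$interpolants[[object$n_steps + 1L]])
  frames <- c(object$frames[1], endpoints)
  replicate(nsim, simplify = FALSE, {
    lapply(frames, function(f) {
      if (noise_sd > 0) {
        f <- f + array(stats::rnorm(length(f), sd = noise_sd), dim(f))
        f[f < 0] <- 0
      }
      f
    })
  })
}

#' Plot a speed-map slice of a fitted rOMT model
#'
#' Displays the time-averaged advective speed `|v|` on an axial slice.
#'
#' @param x an `"romt"` fit.
#' @param slice slice index along the third axis (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.romt <- function(x, slice = NULL, ...) {
  d <- x$grid$dims
  if (is.null(slice)) slice <- max(1L, d[3] %/% 2L)
  v <- coef(x)
  sp <- array(0, d)
  for (k in seq_len(dim(v)[5])) {
    sp <- sp + sqrt(v[, , , 1, k]^2 + v[, , , 2, k]^2 + v[, , , 3, k]^2)
  }
  sp <- sp / dim(v)[5]
  graphics::image(seq_len(d[1]), seq_len(d[2]), sp[, , slice],
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  main = sprintf("mean speed, slice %d", slice),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
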