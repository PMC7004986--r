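#' Dynamic density series
#'
#' An ordered set of nonnegative 3D intensity volumes with acquisition times,
#' sharing one grid: the "mass" the transport model moves.
#'
#' @param frames list of 3D arrays (or a 4D array, last axis = time).
#' @param times acquisition times per frame (e.g. minutes), strictly
#'   increasing; defaults to `0, 1, 2, ...`.
#' @param grid an `image_grid`; defaults to a unit-voxel grid matching the
#'   frames.
#' @param baseline_count number of pre-contrast frames (used by
#'   [percent_baseline()]).
#' @param units one of `"raw"`, `"percent_baseline"`, `"normalized"`.
#' @return An object of class `"density_series"`.
#' @export
density_series <- function(frames, times = NULL, grid = NULL,
                           baseline_count = 1L,
                           units = c("raw", "percent_baseline", "normalized")) {
  units <- match.arg(units)
  if (is.array(frames) && length(dim(frames)) == 4L) {
    frames <- lapply(seq_len(dim(frames)[4]), function(k) frames[, , , k])
  }
  if (!is.list(frames) || length(frames) < 1L) stop("frames must be a nonempty list")
  if (is.null(grid)) grid <- image_grid(dim(frames[[1]]))
  for (f in frames) check_scalar_field(f, grid, name = "frame")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames) || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame")
  }
  structure(list(frames = frames, times = as.numeric(times), grid = grid,
                 baseline_count = as.integer(baseline_count), units = units),
            class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("<density_series> %d frames (%s), %d x %d x %d grid, t = %g..%g\n",
              length(x$frames), x$units,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.density_series <- function(x) length(x$frames)

#' Convert a raw series to percent of baseline signal
#'
#' Divides each voxel by its mean over the `baseline_count` pre-contrast
#' frames and multiplies by 100. Voxels with zero baseline are set to 0
#' (their count is reported in the `"n_zero_baseline"` attribute).
#'
#' @param series a raw `density_series` with `baseline_count >= 1`.
#' @return The converted series (`units = "percent_baseline"`), baseline
#'   frames retained.
#' @export
percent_baseline <- function(series) {
  stopifnot(inherits(series, "density_series"))
  if (series$units != "raw") stop("series must be in raw units")
  nb <- series$baseline_count
  if (nb < 1L || nb >= length(series$frames)) {
    stop("baseline_count must be >= 1 and smaller than the frame count")
  }
  base <- Reduce(`+`, series$frames[seq_len(nb)]) / nb
  zero <- base <= 0
  out <- series
  out$frames <- lapply(series$frames, function(f) {
    r <- 100 * f / base
    r[zero] <- 0
    r
  })
  out$units <- "percent_baseline"
  attr(out, "n_zero_baseline") <- sum(zero)
  out
}

#' Normalize frames to equal total intensity
#'
#' Scales every frame so its voxel sum equals the first frame's sum, the
#' mass-balance precondition of the transport model. Scale factors are
#' attached as attribute `"scale_factors"`.
#'
#' @param series a `density_series` with nonnegative frames.
#' @return The normalized series.
#' @export
normalize_total_intensity <- function(series) {
  stopifnot(inherits(series, "density_series"))
  sums <- vapply(series$frames, sum, numeric(1))
  if (any(sums <= 0)) stop("cannot normalize a frame with nonpositive total intensity")
  sc <- sums[1] / sums
  out <- series
  out$frames <- Map(function(f, s) f * s, series$frames, sc)
  out$units <- "normalized"
  attr(out, "scale_factors") <- sc
  out
}

# Reflect-padded separable 1D convolution along one axis; conserves total
# mass for symmetric normalized kernels.
conv_axis <- function(f, axis, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(f)
  m <- dim(f)[axis]
  idx <- c(rev(seq_len(min(r, m))), seq_len(m), rev(m + 1L - seq_len(min(r, m))))
  if (m < r) { # tiny axis: extend by repeated reflection
    full <- seq_len(m)
    while (length(idx) < m + 2L * r) idx <- c(rev(full), idx, rev(full))
    mid <- (length(idx) - m) %/% 2L
    idx <- idx[(mid - r + 1L):(mid + m + r)]
  }
  padded <- index_axis(f, axis, idx)
  out <- array(0, dim(f))
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * index_axis(padded, axis, (k - 1L) + seq_len(m))
  }
  out
}

gaussian_kernel <- function(sd_vox) {
  r <- max(1L, ceiling(3 * sd_vox))
  k <- exp(-0.5 * ((-r):r / sd_vox)^2)
  k / sum(k)
}

#' Isotropic Gaussian smoothing of a series
#'
#' Per-frame separable Gaussian convolution with reflective (zero-flux)
#' boundary handling, which conserves each frame's total mass.
#'
#' @param series a `density_series` (or a single 3D array with `grid`).
#' @param fwhm full width at half maximum of the kernel, in world units.
#' @param grid required when `series` is a bare array.
#' @return Smoothed series (or array).
#' @export
gaussian_smooth <- function(series, fwhm, grid = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (is.array(series)) {
    if (is.null(grid)) grid <- image_grid(dim(series))
    return(smooth_one(series, grid, fwhm))
  }
  stopifnot(inherits(series, "density_series"))
  out <- series
  out$frames <- lapply(series$frames, smooth_one, grid = series$grid, fwhm = fwhm)
  out
}

smooth_one <- function(f, grid, fwhm) {
  if (fwhm == 0) return(f)
  sd_vox <- fwhm / (2 * sqrt(2 * log(2))) / grid$dx
  k <- gaussian_kernel(sd_vox)
  for (a in 1:3) if (grid$dims[a] > 1L) f <- conv_axis(f, a, k)
  f
}

#' Crop a series to an analysis window
#'
#' Returns the frames covering `[start_time, start_time + duration]`. When
#' `start_time` is NULL the window starts at the peak frame: the frame with
#' maximal mean signal (over `mask` if given), the standard choice of
#' analysis onset for tracer series.
#'
#' @param series a `density_series`.
#' @param start_time window start (same units as `series$times`), or NULL
#'   for the peak frame.
#' @param duration window length; `0` selects a single frame.
#' @param mask optional logical array restricting the peak-signal search.
#' @return The cropped series.
#' @export
crop_to_window <- function(series, start_time = NULL, duration, mask = NULL) {
  stopifnot(inherits(series, "density_series"))
  t <- series$times
  if (is.null(start_time)) {
    means <- vapply(series$frames, function(f) {
      if (is.null(mask)) mean(f) else mean(f[mask])
    }, numeric(1))
    start_time <- t[which.max(means)]
  }
  if (duration < 0) stop("duration must be >= 0")
  end_time <- start_time + duration
  if (start_time < t[1] - 1e-9 || start_time > t[length(t)] + 1e-9) {
    stop("window start lies outside the acquisition span")
  }
  keep <- which(t >= start_time - 1e-9 & t <= end_time + 1e-9)
  if (length(keep) == 0L) stop("window contains no frames")
  out <- series
  out$frames <- series$frames[keep]
  out$times <- t[keep]
  out$baseline_count <- 0L
  out
}
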