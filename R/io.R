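#' Read a 4D NIfTI series
#'
#' Builds a `density_series` from a 4D NIfTI file (or a list of 3D volume
#' files with consistent headers). The grid is derived from the header:
#' voxel size must be isotropic (uniform `dx` is assumed throughout the
#' transport model), and all voxels must be finite.
#'
#' @param path a 4D NIfTI file, or a character vector of 3D volume files.
#' @param times frame times; defaults to the header TR spacing or
#'   `0, 1, ...`.
#' @param baseline_count number of pre-contrast frames.
#' @return A `density_series`.
#' @export
read_series <- function(path, times = NULL, baseline_count = 1L) {
  imgs <- lapply(path, RNifti::readNifti)
  if (length(imgs) == 1L && length(dim(imgs[[1]])) == 4L) {
    img <- imgs[[1]]
    frames <- lapply(seq_len(dim(img)[4]), function(k) array(img[, , , k], dim(img)[1:3]))
    hdr <- img
  } else {
    dims <- lapply(imgs, dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
      stop("frame volumes have mismatched shapes")
    }
    frames <- lapply(imgs, function(x) array(as.numeric(x), dim(x)[1:3]))
    hdr <- imgs[[1]]
  }
  pd <- RNifti::pixdim(hdr)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    stop(sprintf("anisotropic voxels (%s): uniform dx is assumed",
                 paste(signif(pd, 4), collapse = " x ")))
  }
  nbad <- sum(!vapply(frames, function(f) all(is.finite(f)), logical(1)))
  if (nbad > 0) {
    counts <- sum(vapply(frames, function(f) sum(!is.finite(f)), numeric(1)))
    stop(sprintf("series contains %d non-finite voxels", counts))
  }
  affine <- tryCatch(unclass(RNifti::xform(hdr)), error = function(e) NULL)
  grid <- image_grid(dim(frames[[1]]), dx = pd[1], affine = affine)
  density_series(frames, times = times, grid = grid,
                 baseline_count = baseline_count)
}

#' Write a series (or fields) as NIfTI
#'
#' @param x a `density_series`, a single 3D array, or a list of 3D arrays
#'   (written as a 4D volume).
#' @param path output `.nii`/`.nii.gz` path.
#' @param grid grid supplying voxel size when `x` is not a series.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, grid = NULL) {
  if (inherits(x, "density_series")) {
    grid <- x$grid
    x <- x$frames
  }
  if (is.list(x)) x <- array(unlist(x), c(dim(x[[1]]), length(x)))
  if (is.null(grid)) grid <- image_grid(dim(x)[1:3])
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(grid$dx, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export pathlines as ASCII VTK polylines
#'
#' Writes the pathlines of a set, with per-point speed scalars, in the
#' legacy VTK polydata format (world coordinates).
#'
#' @param pset a `"pathline_set"`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_pathlines_vtk <- function(pset, path) {
  stopifnot(inherits(pset, "pathline_set"))
  pts <- do.call(rbind, lapply(pset$pathlines, `[[`, "points"))
  npts <- vapply(pset$pathlines, function(p) nrow(p$points), integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pathlines with speed scalars", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", sum(npts))), con)
  if (sum(npts) > 0) {
    utils::write.table(format(pts, scientific = FALSE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  offsets <- c(0L, cumsum(npts))
  writeLines(sprintf("LINES %d %d", length(npts), length(npts) + sum(npts)), con)
  for (i in seq_along(npts)) {
    writeLines(paste(c(npts[i], seq.int(offsets[i], length.out = npts[i])),
                     collapse = " "), con)
  }
  writeLines(c(sprintf("POINT_DATA %d", sum(npts)),
               "SCALARS speed float 1", "LOOKUP_TABLE default"), con)
  speeds <- unlist(lapply(pset$pathlines, `[[`, "speeds"))
  if (length(speeds)) writeLines(format(speeds, scientific = FALSE), con)
  invisible(path)
}
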