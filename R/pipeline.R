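#' Run the full transport-analysis pipeline
#'
#' Drives preprocess -> rOMT fit -> augmented-velocity pathlines ->
#' clustering/filtering -> rasterization -> per-mask summaries (-> boundary
#' flux when compartment masks are given) from a single configuration, and
#' records a run manifest (config, seed, stage timings, output checksums).
#' Input is either a NIfTI series on disk or a self-contained phantom
#' specification; reruns with the same config and seed are identical.
#'
#' @param config a configuration list or the path of a YAML/JSON file.
#'   Sections: `phantom` (kind `"translation"` or `"diffusion"`, `dims`,
#'   `sd`, `shift`, `sigma2_true`, `n_frames`, `background`, `noise_sd`) or
#'   `input` (`path`, `times`, `baseline_count`); `preprocess`
#'   (`percent_baseline`, `normalize`, `fwhm`); `solver` (`sigma2`, `xi`,
#'   `n_steps`, `psi`, `max_iter`); `glad` (`threshold`, `stride`,
#'   `cluster_threshold`, `min_cluster_size`); `masks` (named NIfTI paths);
#'   `flux` (`from`, `to` mask names); `seed`; `output_dir`.
#' @return The run manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- config
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out_dir <- if (is.null(cfg$output_dir)) "romt_output" else cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, seed = seed,
                   version = as.character(utils::packageVersion("romt")),
                   stages = list(), outputs = list())
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    manifest$stages[[name]] <<- round(tic() - t0, 3)
  }

  # --- input -----------------------------------------------------------
  t0 <- tic()
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    dims <- if (is.null(ph$dims)) c(24L, 24L, 24L) else as.integer(ph$dims)
    grid <- image_grid(dims)
    series <- switch(if (is.null(ph$kind)) "translation" else ph$kind,
      diffusion = make_diffusion_phantom(
        grid, sd = ph$sd %||% 3, sigma2_true = ph$sigma2_true %||% 0.5,
        n_frames = ph$n_frames %||% 3L),
      translation = make_translation_phantom(
        grid, center = ph$center %||% c(8, dims[2] / 2, dims[3] / 2),
        sd = ph$sd %||% 3, shift = ph$shift %||% c(2, 0, 0),
        sigma2_true = ph$sigma2_true %||% 0.02,
        n_frames = ph$n_frames %||% 3L,
        background = ph$background %||% 0),
      stop("unknown phantom kind"))
    if (!is.null(ph$noise_sd) && ph$noise_sd > 0) {
      series <- add_noise(series, ph$noise_sd, seed = seed)
    }
  } else if (!is.null(cfg$input)) {
    series <- read_series(cfg$input$path, times = cfg$input$times,
                          baseline_count = cfg$input$baseline_count %||% 1L)
  } else stop("config needs a 'phantom' or 'input' section")
  stage("input", t0)

  # --- preprocess ------------------------------------------------------
  t0 <- tic()
  pp <- cfg$preprocess
  pct <- NULL
  if (isTRUE(pp$percent_baseline)) {
    pct <- percent_baseline(series)
    series <- pct
  }
  if (!is.null(pp$fwhm) && pp$fwhm > 0) series <- gaussian_smooth(series, pp$fwhm)
  if (is.null(pp$normalize) || isTRUE(pp$normalize)) {
    series <- normalize_total_intensity(series)
  }
  stage("preprocess", t0)

  # --- solve -----------------------------------------------------------
  t0 <- tic()
  sv <- cfg$solver
  ctrl <- romt_control()
  if (!is.null(sv$max_iter)) ctrl$max_iter <- as.integer(sv$max_iter)
  fit <- romt(series, sigma2 = sv$sigma2 %||% 0.002, xi = sv$xi %||% 50,
              n_steps = sv$n_steps %||% 10L, psi = sv$psi %||% 1,
              control = ctrl)
  stage("solve", t0)

  # --- pathlines -------------------------------------------------------
  t0 <- tic()
  gl <- cfg$glad
  if (!is.null(pct)) {
    seeds <- select_start_points(pct, threshold = gl$threshold %||% 0.12,
                                 stride = gl$stride %||% 1L)
  } else {
    mu0 <- series$frames[[1]]
    sel <- mu0 >= (gl$seed_frac %||% 0.1) * max(mu0)
    seeds <- arrayInd(which(sel), fit$grid$dims)
  }
  if (nrow(seeds) == 0L) {
    pset <- structure(list(pathlines = list(), grid = fit$grid,
                           provenance = list()), class = "pathline_set")
  } else {
    pset <- integrate_pathlines(fit, seeds)
    pset <- cluster_and_filter(
      pset, cluster_threshold = gl$cluster_threshold %||% (2 * fit$grid$dx),
      min_cluster_size = gl$min_cluster_size %||% 5L)
  }
  stage("pathlines", t0)

  # --- rasterize + summaries ------------------------------------------
  t0 <- tic()
  bin <- rasterize_pathlines(pset, "binary")
  spd <- rasterize_pathlines(pset, "speed")
  masks <- list(whole = array(TRUE, fit$grid$dims))
  if (!is.null(cfg$masks)) {
    masks <- lapply(cfg$masks, function(p) array(as.numeric(RNifti::readNifti(p)) > 0.5,
                                                 fit$grid$dims))
  }
  summ <- summarize_by_mask(bin, spd, masks)
  stage("summaries", t0)

  # --- flux (optional) -------------------------------------------------
  flux <- NULL
  if (!is.null(cfg$flux)) {
    t0 <- tic()
    bd <- extract_boundary(masks[[cfg$flux$from]], masks[[cfg$flux$to]],
                           fit$grid)
    flux <- net_directed_influx(fit, bd)
    stage("flux", t0)
  }

  # --- outputs ---------------------------------------------------------
  t0 <- tic()
  paths <- c(
    binary = file.path(out_dir, "pathline_network.nii.gz"),
    speed = file.path(out_dir, "speed_map.nii.gz"),
    pathlines = file.path(out_dir, "pathlines.vtk"),
    summary = file.path(out_dir, "summary.csv"))
  write_nifti(bin, paths[["binary"]], grid = fit$grid)
  write_nifti(spd, paths[["speed"]], grid = fit$grid)
  write_pathlines_vtk(pset, paths[["pathlines"]])
  utils::write.csv(summ, paths[["summary"]], row.names = FALSE)
  if (!is.null(flux)) {
    paths[["flux"]] <- file.path(out_dir, "flux_curve.csv")
    utils::write.csv(flux$curve, paths[["flux"]], row.names = FALSE)
  }
  conv <- do.call(rbind, lapply(seq_along(fit$pairs), function(p)
    cbind(pair = p, fit$pairs[[p]]$convergence)))
  paths[["convergence"]] <- file.path(out_dir, "convergence.json")
  jsonlite::write_json(conv, paths[["convergence"]], digits = NA)
  manifest$outputs <- lapply(as.list(paths), function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  stage("write", t0)

  manifest$summary <- summ
  if (!is.null(flux)) manifest$net_influx <- flux$total
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
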