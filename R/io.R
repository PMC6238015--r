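# File formats and the reproducible end-to-end pipeline: NIfTI volumes
# with a frame-schedule CSV sidecar, YAML/JSON configuration, JSON
# summaries and manifests.

schedule_path_for <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_frames.csv")
}

#' Write / read a dynamic series as NIfTI + schedule sidecar
#'
#' The 4D activity array is stored as a NIfTI file (float32) with the
#' voxel size in its header; the frame schedule travels in a sidecar CSV
#' (`<base>_frames.csv` with columns `frame_index, start_min, end_min`)
#' because time metadata in volumetric headers is unreliable across
#' tools.
#'
#' @param series a [dynamic_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_dynamic_series` invisibly returns `path`;
#'   `read_dynamic_series` returns a [dynamic_series()].
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  RNifti::writeNifti(nifti_with_pixdim(series$frames, series$voxel_size), path)
  utils::write.csv(data.frame(frame_index = seq_along(series$frame_starts),
                              start_min = series$frame_starts,
                              end_min = series$frame_ends),
                   schedule_path_for(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_dynamic_series
#' @param schedule_path schedule CSV; defaults to the sidecar next to
#'   `path`.
#' @export
read_dynamic_series <- function(path, schedule_path = NULL) {
  schedule_path <- schedule_path %||% schedule_path_for(path)
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  assert_that(file.exists(schedule_path),
              sprintf("missing frame-schedule sidecar: %s", schedule_path))
  img <- RNifti::readNifti(path)
  frames <- array(as.numeric(img), dim(img))
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  sched <- utils::read.csv(schedule_path)
  need <- c("frame_index", "start_min", "end_min")
  assert_that(all(need %in% names(sched)),
              sprintf("schedule must have columns: %s", paste(need, collapse = ", ")))
  assert_that(nrow(sched) == dim(frames)[4],
              sprintf("schedule has %d frames but the file has %d",
                      nrow(sched), dim(frames)[4]))
  vs <- attr(img, "pixdim")[1:3]
  dynamic_series(frames, sched$start_min, sched$end_min, voxel_size = vs)
}

#' Write a 3D volume as NIfTI
#' @param vol numeric 3D array.
#' @param path output path.
#' @param voxel_size mm triplet.
#' @export
write_volume <- function(vol, path, voxel_size = c(4, 4, 4)) {
  RNifti::writeNifti(nifti_with_pixdim(vol, voxel_size), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

# Build a float32 NIfTI image carrying the voxel size in its header.
nifti_with_pixdim <- function(arr, voxel_size, time_step = 1) {
  h <- RNifti::niftiHeader(RNifti::asNifti(arr, datatype = "float"))
  nd <- length(dim(arr))
  pd <- h$pixdim
  pd[2:4] <- voxel_size
  if (nd >= 4L) pd[5] <- time_step
  h$pixdim <- pd
  RNifti::asNifti(arr, reference = h, datatype = "float")
}

#' Write / read a tri-exponential model as JSON
#' @param model a [triexp_input()].
#' @param path JSON file path.
#' @export
write_triexp <- function(model, path) {
  stopifnot(inherits(model, "triexp_input"))
  jsonlite::write_json(list(A1 = model$A[1], A2 = model$A[2], A3 = model$A[3],
                            lambda1 = model$lambda[1], lambda2 = model$lambda[2],
                            lambda3 = model$lambda[3], t0 = model$t0),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_triexp
#' @export
read_triexp <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  triexp_input(c(j$A1, j$A2, j$A3), c(j$lambda1, j$lambda2, j$lambda3),
               j$t0 %||% 0)
}

#' Write a kinetic map as NIfTI volumes + JSON summary
#'
#' Writes `ki.nii.gz`, `vp.nii.gz` (NA outside the mask stored as -1) and
#' `summary.json` (maxima, their 1-based voxel coordinates, draw count
#' and seed) into `dir`.
#'
#' @param map a `kinetic_map`.
#' @param dir output directory (created if needed).
#' @param voxel_size mm triplet.
#' @return invisibly, the directory.
#' @export
write_kinetic_map <- function(map, dir, voxel_size = c(4, 4, 4)) {
  stopifnot(inherits(map, "kinetic_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ki <- map$ki_map; ki[is.na(ki)] <- -1
  vp <- map$vp_map; vp[is.na(vp)] <- -1
  write_volume(ki, file.path(dir, "ki.nii.gz"), voxel_size)
  write_volume(vp, file.path(dir, "vp.nii.gz"), voxel_size)
  jsonlite::write_json(list(ki_max = map$ki_max, ki_max_voxel = map$ki_max_coord,
                            vp_max = map$vp_max, vp_max_voxel = map$vp_max_coord,
                            n_draws = map$n_draws, seed = map$seed),
                       file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

default_config <- function() {
  list(
    phantom = list(shape = c(32, 32, 16),
                   lesion = list(center = c(16, 16, 8), radius = 4,
                                 ki = 0.05, vp = 0.3),
                   background = list(ki = 0.002, vp = 0.05),
                   aorta = list(center_xy = c(6, 6), radius = 2),
                   voxel_size = c(4, 4, 4)),
    input_function = list(A = c(90000, 18000, 3300),
                          lambda = c(3.0, 0.3, 0.009), t0 = 0),
    acquisition = list(start_min = 80, duration_min = 15, subframe_min = 0.25),
    noise = list(alpha = 300, floor = 0),
    registration = list(enabled = FALSE, max_shift = 3),
    estimator = list(method = "parapet", n_draws = 1000, seed = 1,
                     sigma_p_mode = "per_timepoint"),
    seed = 1
  )
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

#' Read a run configuration (YAML or JSON)
#'
#' Unspecified fields fall back to the package defaults (small phantom,
#' default input-function shape, 80-min 15-min acquisition, clinical-like
#' noise, voxel estimator at 1000 draws). Validation happens before any
#' compute.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @return a validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    assert_that(file.exists(path), sprintf("no such config file: %s", path))
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- merge_config(cfg, user)
  }
  assert_that(cfg$acquisition$duration_min > 0 && cfg$acquisition$subframe_min > 0,
              "acquisition durations must be positive")
  assert_that(cfg$estimator$n_draws >= 1, "n_draws must be >= 1")
  for (p in c(cfg$series_path, cfg$lesion_mask_path, cfg$aorta_mask_path)) {
    assert_that(file.exists(p), sprintf("configured path does not exist: %s", p))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$estimator$seed <- as.integer(cfg$estimator$seed)
  cfg
}

stage_log <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] start", stage))
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done (%.1f s)", stage, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full simulate-estimate-compare pipeline
#'
#' Stages: simulate (or load) the dynamic series, rebin into overlapping
#' windows, optional mutual-information realignment, IDIF extraction,
#' kinetic estimation with the configured method, and comparison of the
#' voxel map against the Patlak reference at the lesion maximum. All
#' outputs (maps, IDIF table, summary and manifest JSON) are written
#' under `out_dir`; identical configurations produce identical outputs.
#'
#' @param config a config list from [read_run_config()] (or `NULL` for
#'   defaults).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return invisible list with the phantom, series, statistics, IDIF,
#'   estimate(s) and summary.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) default_config() else config
  fn <- triexp_input(cfg$input_function$A, cfg$input_function$lambda,
                     cfg$input_function$t0)

  sim <- stage_log("simulate", {
    phantom <- make_phantom(shape = cfg$phantom$shape,
                            lesion_spec = cfg$phantom$lesion,
                            background = cfg$phantom$background,
                            aorta = cfg$phantom$aorta,
                            voxel_size = cfg$phantom$voxel_size,
                            seed = cfg$seed)
    sched <- default_schedule(cfg$acquisition$start_min, cfg$acquisition$duration_min,
                              cfg$acquisition$subframe_min)
    noise <- if (cfg$noise$alpha > 0 || cfg$noise$floor > 0) {
      noise_model(cfg$noise$alpha, cfg$noise$floor)
    }
    series <- simulate_series(phantom, fn, sched, noise, seed = cfg$seed)
    list(phantom = phantom, series = series)
  })

  stats <- stage_log("rebin", frame_statistics(sim$series))

  reg <- NULL
  if (isTRUE(cfg$registration$enabled)) {
    reg <- stage_log("register", register_to_central(stats,
                                                     max_shift = cfg$registration$max_shift))
    stats <- reg$stats
  }

  idif <- stage_log("idif", idif_from_roi(stats, sim$phantom$aorta_mask))

  est <- stage_log("estimate", {
    method <- cfg$estimator$method
    switch(method,
      parapet = parapet_voxel(stats, idif, sim$phantom$lesion_mask, fn,
                              n_draws = cfg$estimator$n_draws,
                              seed = cfg$estimator$seed),
      `barbolosi-im` = barbolosi_lesion(stats, sim$phantom$lesion_mask, idif, fn,
                                        n_draws = cfg$estimator$n_draws,
                                        seed = cfg$estimator$seed),
      stop(sprintf("unknown estimator method in config: %s", method), call. = FALSE))
  })

  summary <- stage_log("compare", {
    t_k <- stats$bin_mid_times
    fn_scaled <- scale_to_samples(fn, idif$t, idif$c_p_mean)
    out <- list(method = cfg$estimator$method,
                n_draws = cfg$estimator$n_draws, seed = cfg$seed)
    if (inherits(est, "kinetic_map")) {
      # Patlak reference at the voxel of the Ki maximum, and map maximum
      vox <- est$ki_max_coord
      c_fdg <- vapply(stats$mean_images, function(img) img[vox[1], vox[2], vox[3]], 0)
      meas <- measurement_set(t_k, c_fdg, rep(0, length(t_k)),
                              idif$c_p_mean, rep(0, length(t_k)),
                              integrate_cp(fn_scaled, t_k))
      pat <- patlak_fit(meas)
      out$ki_max <- est$ki_max
      out$ki_max_voxel <- est$ki_max_coord
      out$vp_max <- est$vp_max
      out$patlak_ki_at_max_voxel <- pat$ki
      out$ki_ratio_to_patlak <- est$ki_max / pat$ki
      out$true_ki_lesion <- cfg$phantom$lesion$ki
    } else {
      out$ki <- est$ki
      out$vp <- est$vp
      out$ki_sd <- est$ki_sd
      out$vp_sd <- est$vp_sd
    }
    out
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(est, "kinetic_map")) {
      write_kinetic_map(est, out_dir, cfg$phantom$voxel_size)
    }
    utils::write.csv(as.data.frame(idif), file.path(out_dir, "idif.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = cfg,
                     package_version = as.character(utils::packageVersion("parapet")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(phantom = sim$phantom, series = sim$series, stats = stats,
                 registration = reg, idif = idif, estimate = est,
                 summary = summary, config = cfg))
}
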