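# Synthetic dynamic-PET phantom: ground-truth kinetic maps, the linear
# irreversible-trapping forward model, count-statistics noise and per-bin
# rigid motion. Everything downstream is testable against this generator.

#' Phantom ground truth
#'
#' Voxelwise kinetic ground truth on a regular grid: a net influx rate map
#' `ki_map` (mL_blood/mL_tissue/min), a blood distribution volume map
#' `vp_map` (unitless), and binary lesion / necrotic-core / aorta masks.
#' Aorta voxels carry `ki = 0, vp = 1`, so in a noiseless series they
#' reproduce the blood curve exactly and can serve as the IDIF region.
#'
#' @param shape integer triplet, grid size (x, y, z); z is the slice axis.
#' @param lesion_spec a list (or list of lists) describing lesions:
#'   `center` (voxel coords), `radius` (voxels, > 0), `ki`, `vp`, and
#'   optionally `necrotic = list(radius, ki, vp)` for a central core with
#'   reduced uptake.
#' @param background list with `ki`, `vp` for non-lesion tissue.
#' @param aorta list with `center_xy` (voxel coords) and `radius` (voxels)
#'   of a z-axis cylinder, or `NULL` for no aorta.
#' @param ki_heterogeneity multiplicative lognormal spread (sdlog) applied
#'   to lesion ki voxels; 0 (default) gives a homogeneous lesion.
#' @param voxel_size mm triplet.
#' @param seed integer seed (used only when `ki_heterogeneity > 0`).
#' @return object of class `phantom_truth` with fields `ki_map`, `vp_map`,
#'   `lesion_mask`, `necrotic_mask`, `aorta_mask`, `voxel_size`.
#' @examples
#' ph <- make_phantom(c(32, 32, 16),
#'                    lesion_spec = list(center = c(16, 16, 8), radius = 4,
#'                                       ki = 0.05, vp = 0.3))
#' sum(ph$lesion_mask)
#' @export
make_phantom <- function(shape = c(32, 32, 16),
                         lesion_spec = list(center = c(16, 16, 8), radius = 4,
                                            ki = 0.05, vp = 0.3),
                         background = list(ki = 0.002, vp = 0.05),
                         aorta = list(center_xy = c(6, 6), radius = 2),
                         ki_heterogeneity = 0,
                         voxel_size = c(4, 4, 4),
                         seed = 1L) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3L && all(shape > 0), "shape must be a positive integer triplet")
  assert_that(background$ki >= 0 && background$vp >= 0, "background ki/vp must be >= 0")
  if (!is.null(lesion_spec$center)) lesion_spec <- list(lesion_spec)

  ki <- array(background$ki, shape)
  vp <- array(background$vp, shape)
  lesion_mask <- array(FALSE, shape)
  necrotic_mask <- array(FALSE, shape)

  for (les in lesion_spec) {
    assert_that(!is.null(les$center) && !is.null(les$radius), "lesion needs center and radius")
    assert_that(les$radius > 0, "lesion radius must be > 0")
    assert_that(les$ki >= 0 && les$vp >= 0, "lesion ki/vp must be >= 0")
    assert_that(all(les$center - les$radius >= 1) && all(les$center + les$radius <= shape),
                "lesion extends outside the grid")
    m <- sphere_mask(shape, les$center, les$radius)
    lesion_mask <- lesion_mask | m
    ki[m] <- les$ki
    vp[m] <- les$vp
    if (!is.null(les$necrotic)) {
      nec <- les$necrotic
      assert_that(nec$radius > 0 && nec$radius < les$radius,
                  "necrotic radius must be positive and smaller than the lesion radius")
      nk <- nec$ki %||% 0
      nv <- nec$vp %||% les$vp
      assert_that(nk >= 0 && nv >= 0, "necrotic ki/vp must be >= 0")
      nm <- sphere_mask(shape, nec$center %||% les$center, nec$radius)
      necrotic_mask <- necrotic_mask | nm
      ki[nm] <- nk
      vp[nm] <- nv
    }
  }

  if (ki_heterogeneity > 0) {
    with_seed(seed, {
      idx <- which(lesion_mask & !necrotic_mask)
      ki[idx] <- ki[idx] * stats::rlnorm(length(idx), 0, ki_heterogeneity)
    })
  }

  aorta_mask <- array(FALSE, shape)
  if (!is.null(aorta)) {
    aorta_mask <- cylinder_mask_z(shape, aorta$center_xy, aorta$radius)
    assert_that(!any(aorta_mask & lesion_mask), "aorta overlaps a lesion; move it")
    ki[aorta_mask] <- 0
    vp[aorta_mask] <- 1
  }

  structure(list(ki_map = ki, vp_map = vp, lesion_mask = lesion_mask,
                 necrotic_mask = necrotic_mask, aorta_mask = aorta_mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom %s voxels (%s mm): lesion %d vox, necrotic %d vox, aorta %d vox\n",
              paste(dim(x$ki_map), collapse = "x"),
              paste(x$voxel_size, collapse = "x"),
              sum(x$lesion_mask), sum(x$necrotic_mask), sum(x$aorta_mask)))
  invisible(x)
}

#' Dynamic PET series
#'
#' A 4D activity array (Bq/mL) with its frame schedule in minutes
#' post-injection. Frame values are interpreted as samples at the frame
#' mid-times (the fine "listmode-like" subframe grid).
#'
#' @param frames 4D numeric array (x, y, z, frame).
#' @param frame_starts,frame_ends frame start/stop times (min), strictly
#'   increasing and non-overlapping.
#' @param voxel_size mm triplet.
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, frame_starts, frame_ends, voxel_size = c(4, 4, 4)) {
  assert_that(length(dim(frames)) == 4L, "frames must be a 4D array")
  n <- dim(frames)[4]
  assert_that(length(frame_starts) == n && length(frame_ends) == n,
              "frame schedule length must equal the number of 3D frames")
  assert_that(all(frame_ends > frame_starts), "frame_ends must exceed frame_starts")
  assert_that(all(diff(frame_starts) > 0), "frame_starts must be strictly increasing")
  assert_that(all(frame_starts[-1] >= frame_ends[-n] - 1e-9),
              "frames must not overlap")
  structure(list(frames = frames,
                 frame_starts = as.numeric(frame_starts),
                 frame_ends = as.numeric(frame_ends),
                 voxel_size = as.numeric(voxel_size)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dynamic series %dx%dx%d, %d frames, %.2f-%.2f min post-injection\n",
              d[1], d[2], d[3], d[4], x$frame_starts[1], x$frame_ends[d[4]]))
  invisible(x)
}

#' Default late-acquisition schedule
#'
#' The fine temporal sampling emulating a listmode acquisition: by default
#' 60 subframes of 15 s covering 80--95 min post-injection.
#' @param start acquisition start (min post-injection).
#' @param duration acquisition length (min).
#' @param subframe subframe length (min).
#' @return list with `starts`, `ends`, `mids` (min).
#' @export
default_schedule <- function(start = 80, duration = 15, subframe = 0.25) {
  assert_that(duration > 0 && subframe > 0, "duration and subframe must be positive")
  n <- round(duration / subframe)
  assert_that(abs(n * subframe - duration) < 1e-9, "subframe must divide duration")
  starts <- start + subframe * (seq_len(n) - 1)
  list(starts = starts, ends = starts + subframe, mids = starts + subframe / 2)
}

#' Noiseless forward model of the irreversible three-compartment system
#'
#' Under the linearized irreversible-trapping model, voxel activity at
#' time t is `C(t) = ki * integral_0^t Cp + vp * Cp(t)`. Each requested
#' sample time yields one 3D frame; aorta voxels (ki = 0, vp = 1)
#' reproduce `Cp(t)` exactly.
#'
#' @param truth a [make_phantom()] result.
#' @param input_fn a [triexp_input()].
#' @param times sample times (min), non-negative, `>= t0`; interpreted as
#'   frame mid-times.
#' @param frame_starts,frame_ends optional explicit schedule; by default
#'   inferred from the (uniform) spacing of `times`.
#' @return a noiseless [dynamic_series()].
#' @export
forward_model <- function(truth, input_fn, times, frame_starts = NULL, frame_ends = NULL) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(input_fn, "triexp_input"))
  assert_that(all(times >= 0), "negative sample times are not allowed")
  times <- as.numeric(times)
  cp <- evaluate_cp(input_fn, times)
  icp <- integrate_cp(input_fn, times)
  shape <- dim(truth$ki_map)
  n <- length(times)
  frames <- array(0, c(shape, n))
  for (k in seq_len(n)) {
    frames[, , , k] <- truth$ki_map * icp[k] + truth$vp_map * cp[k]
  }
  if (is.null(frame_starts)) {
    dt <- if (n > 1) diff(times) else 1
    assert_that(n == 1 || max(abs(dt - dt[1])) < 1e-9,
                "times must be uniformly spaced when no explicit schedule is given")
    half <- (if (n > 1) dt[1] else 1) / 2
    frame_starts <- times - half
    frame_ends <- times + half
  }
  dynamic_series(frames, frame_starts, frame_ends, truth$voxel_size)
}

#' Measurement-noise model
#'
#' Gaussian noise surrogate for reconstruction/count statistics: the
#' variance of a frame value is `alpha * activity / duration + floor`,
#' i.e. inversely proportional to frame duration as for counting noise.
#'
#' @param alpha variance scale (Bq/mL . min per unit activity), >= 0. The
#'   default 300 gives ~10% voxel CV on a 2-min frame at 15 kBq/mL,
#'   a typical clinical lesion level.
#' @param floor minimum variance (Bq^2/mL^2), >= 0.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(alpha = 300, floor = 0) {
  assert_that(alpha >= 0 && floor >= 0, "alpha and floor must be >= 0")
  structure(list(alpha = alpha, floor = floor), class = "noise_model")
}

#' Add measurement noise to a dynamic series
#'
#' Adds zero-mean Gaussian noise with variance
#' `alpha * clean / duration + floor` per voxel and frame, then clips at
#' zero (activity concentrations are non-negative). Reproducible under
#' `seed`.
#'
#' @param series a [dynamic_series()].
#' @param model a [noise_model()].
#' @param seed integer seed.
#' @param frame_durations frame durations (min); defaults to the series
#'   schedule. Must be positive.
#' @return a noisy [dynamic_series()].
#' @export
add_noise <- function(series, model, seed = 1L, frame_durations = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(model, "noise_model"))
  dur <- frame_durations %||% (series$frame_ends - series$frame_starts)
  assert_that(all(dur > 0), "frame durations must be positive")
  d <- dim(series$frames)
  dur_full <- rep(dur, each = prod(d[1:3]))
  sigma2 <- model$alpha * pmax(series$frames, 0) / dur_full + model$floor
  noisy <- with_seed(seed, series$frames + stats::rnorm(length(sigma2), 0, sqrt(sigma2)))
  noisy <- pmax(noisy, 0)
  dim(noisy) <- d
  dynamic_series(noisy, series$frame_starts, series$frame_ends, series$voxel_size)
}

#' Apply per-bin rigid translation (simulated patient motion)
#'
#' Splits the series into `nrow(shifts_mm)` equal contiguous temporal
#' bins and translates every frame of bin b by its mm shift (trilinear
#' interpolation, zero fill at the field-of-view edge). Used to test
#' registration recovery.
#'
#' @param series a [dynamic_series()].
#' @param shifts_mm numeric matrix, one row per temporal bin, columns
#'   (x, y, z) in mm.
#' @return the shifted [dynamic_series()].
#' @export
apply_motion <- function(series, shifts_mm) {
  stopifnot(inherits(series, "dynamic_series"))
  shifts_mm <- rbind(shifts_mm)
  n_bins <- nrow(shifts_mm)
  n <- dim(series$frames)[4]
  assert_that(n %% n_bins == 0,
              sprintf("number of frames (%d) is not divisible into %d bins", n, n_bins))
  per_bin <- n / n_bins
  frames <- series$frames
  for (b in seq_len(n_bins)) {
    sh_vox <- shifts_mm[b, ] / series$voxel_size
    if (all(abs(sh_vox) < 1e-12)) next
    for (k in ((b - 1) * per_bin + 1):(b * per_bin)) {
      frames[, , , k] <- translate_volume(series$frames[, , , k], sh_vox)
    }
  }
  dynamic_series(frames, series$frame_starts, series$frame_ends, series$voxel_size)
}

#' One-call phantom simulation
#'
#' Convenience wrapper: forward model on the default fine schedule, plus
#' optional noise and motion.
#'
#' @param truth a [make_phantom()] result.
#' @param input_fn a [triexp_input()].
#' @param schedule a [default_schedule()]-style list.
#' @param noise a [noise_model()] or `NULL` for a noiseless series.
#' @param shifts_mm per-bin motion matrix or `NULL`.
#' @param seed integer seed for the noise.
#' @return a [dynamic_series()].
#' @export
simulate_series <- function(truth, input_fn = default_input_function(),
                            schedule = default_schedule(), noise = noise_model(),
                            shifts_mm = NULL, seed = 1L) {
  series <- forward_model(truth, input_fn, schedule$mids, schedule$starts, schedule$ends)
  if (!is.null(shifts_mm)) series <- apply_motion(series, shifts_mm)
  if (!is.null(noise)) series <- add_noise(series, noise, seed = seed)
  series
}
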