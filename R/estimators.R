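# Ki/Vp estimators: Patlak linear reference, Hunter single-time bound,
# box-constrained least squares, Monte-Carlo error propagation, the
# lesion-level (3-slice) estimator and the voxel-level parametric mapper.

#' Measurement set for kinetic estimation
#'
#' Per-time-point tuples feeding the estimators: tissue activity mean and
#' variance, blood activity mean and variance, and the blood-curve
#' integral from injection.
#'
#' @param t time points (min post-injection), strictly increasing.
#' @param c_fdg_mean,c_fdg_var tissue activity mean (Bq/mL) and variance
#'   (Bq^2/mL^2).
#' @param c_p_mean,c_p_var blood activity mean and variance.
#' @param c_p_integral integral of Cp from injection to t (Bq.min/mL),
#'   strictly increasing.
#' @return object of class `measurement_set` (a data frame).
#' @export
measurement_set <- function(t, c_fdg_mean, c_fdg_var, c_p_mean, c_p_var, c_p_integral) {
  n <- length(t)
  assert_that(n >= 2, "at least 2 time points are required")
  lens <- c(length(c_fdg_mean), length(c_fdg_var), length(c_p_mean),
            length(c_p_var), length(c_p_integral))
  assert_that(all(lens == n), "all columns must have one value per time point")
  assert_that(all(diff(t) > 0), "time points must be strictly increasing")
  assert_that(all(c_fdg_var >= 0) && all(c_p_var >= 0), "variances must be >= 0")
  assert_that(all(diff(c_p_integral) > 0), "c_p_integral must be strictly increasing")
  structure(data.frame(t = t, c_fdg_mean = c_fdg_mean, c_fdg_var = c_fdg_var,
                       c_p_mean = c_p_mean, c_p_var = c_p_var,
                       c_p_integral = c_p_integral),
            class = c("measurement_set", "data.frame"))
}

kinetic_estimate <- function(ki, vp, ki_sd = NA_real_, vp_sd = NA_real_,
                             n_draws = NA_integer_, seed = NA_integer_,
                             k_h = NA_real_, degenerate = FALSE) {
  structure(list(ki = ki, vp = vp, ki_sd = ki_sd, vp_sd = vp_sd,
                 n_draws = n_draws, seed = seed, k_h = k_h,
                 degenerate = degenerate),
            class = "kinetic_estimate")
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat(sprintf("Ki = %.5g", x$ki))
  if (is.finite(x$ki_sd)) cat(sprintf(" (sd %.3g)", x$ki_sd))
  cat(sprintf("  Vp = %.4g", x$vp))
  if (is.finite(x$vp_sd)) cat(sprintf(" (sd %.3g)", x$vp_sd))
  cat(" [mL_blood/mL_tissue/min; unitless]\n")
  if (!is.na(x$n_draws)) cat(sprintf("  %d Monte-Carlo draws, seed %d, K_H = %.5g\n",
                                     x$n_draws, x$seed, x$k_h))
  invisible(x)
}

#' Patlak linear fit (reference estimator)
#'
#' Unconstrained ordinary least squares of the tissue activity against
#' the two regressors of the linearized irreversible-trapping model,
#' `C(t_k) = Ki * integral Cp + Vp * Cp(t_k)` (no intercept). Exact on
#' noiseless model data.
#'
#' @param meas a [measurement_set()].
#' @return a `kinetic_estimate` (ki = slope, vp = blood-volume coefficient).
#' @export
patlak_fit <- function(meas) {
  stopifnot(inherits(meas, "measurement_set"))
  X <- cbind(meas$c_p_integral, meas$c_p_mean)
  qr_x <- qr(X)
  assert_that(qr_x$rank == 2L, "design is collinear: integral and Cp columns are not independent")
  beta <- qr.coef(qr_x, meas$c_fdg_mean)
  kinetic_estimate(ki = beta[1], vp = beta[2])
}

#' Hunter single-time-point bound on Ki
#'
#' The single-time estimate `K_H = C(t_1) / integral_0^{t_1} Cp`, which
#' neglects the blood distribution volume (Vp = 0). On noiseless data
#' with Vp > 0 it strictly overestimates Ki, which is what makes it a
#' valid upper bound for the constrained solver.
#'
#' @param meas a [measurement_set()].
#' @return scalar K_H (mL_blood/mL_tissue/min), >= 0.
#' @export
hunter_k <- function(meas) {
  stopifnot(inherits(meas, "measurement_set"))
  assert_that(meas$c_p_integral[1] > 0, "blood integral at the first time point is zero")
  max(meas$c_fdg_mean[1] / meas$c_p_integral[1], 0)
}

# Vectorized box-constrained least squares over many draws.
# Minimizes f(x, y) = sum_k (x I_k + y P_k - C_k)^2 over [0, kh] x [0, Inf)
# by enumerating the KKT patterns (interior, x = 0, x = kh, y = 0; the
# clamps cover the corners). Inputs are n_draws x K matrices; kh a scalar
# or length-n vector. Returns x, y and a degenerate flag.
solve_constrained_batch <- function(Cmat, Pmat, Imat, kh) {
  n <- nrow(Cmat)
  kh <- rep_len(kh, n)
  s_ii <- rowSums(Imat * Imat)
  s_pp <- rowSums(Pmat * Pmat)
  s_ip <- rowSums(Imat * Pmat)
  s_ic <- rowSums(Imat * Cmat)
  s_pc <- rowSums(Pmat * Cmat)

  degenerate <- s_ii <= 0 & s_pp <= 0
  fval <- function(x, y) {
    x * x * s_ii + y * y * s_pp + 2 * x * y * s_ip - 2 * x * s_ic - 2 * y * s_pc
  }

  det <- s_ii * s_pp - s_ip^2
  ok_det <- det > .Machine$double.eps * pmax(s_ii * s_pp, 1)
  # candidate 1: interior (unconstrained) solution where feasible
  x1 <- ifelse(ok_det, (s_ic * s_pp - s_pc * s_ip) / det, NA_real_)
  y1 <- ifelse(ok_det, (s_pc * s_ii - s_ic * s_ip) / det, NA_real_)
  feas1 <- ok_det & x1 >= 0 & x1 <= kh & y1 >= 0
  f1 <- ifelse(feas1, fval(x1, y1), Inf)
  # candidate 2: x = 0 edge (y clamped at 0 covers the origin corner)
  y2 <- ifelse(s_pp > 0, pmax(s_pc / s_pp, 0), 0)
  f2 <- fval(0, y2)
  # candidate 3: x = kh edge
  y3 <- ifelse(s_pp > 0, pmax((s_pc - kh * s_ip) / s_pp, 0), 0)
  f3 <- fval(kh, y3)
  # candidate 4: y = 0 edge, x clamped into [0, kh]
  x4 <- ifelse(s_ii > 0, pmin(pmax(s_ic / s_ii, 0), kh), 0)
  f4 <- fval(x4, 0)

  fmat <- cbind(f1, f2, f3, f4)
  pick <- max.col(-fmat, ties.method = "first")  # interior first on exact ties
  x <- ifelse(pick == 1, x1, ifelse(pick == 2, 0, ifelse(pick == 3, kh, x4)))
  y <- ifelse(pick == 1, y1, ifelse(pick == 2, y2, ifelse(pick == 3, y3, 0)))
  x[degenerate] <- 0
  y[degenerate] <- 0
  list(x = x, y = y, f = fmat[cbind(seq_len(n), pick)], degenerate = degenerate)
}

#' Box-constrained least-squares solution for one draw
#'
#' Global minimizer of `f(x, y) = sum_k (x * intCp_k + y * Cp_k - C_k)^2`
#' over the box `0 <= x <= k_h`, `0 <= y`, found by normal equations plus
#' active-set enumeration of the constraint patterns. Exact ties between
#' patterns resolve toward the interior solution. A fully degenerate
#' system (all-zero regressors) returns (0, 0) with a flag.
#'
#' @param c_fdg tissue activities per time point (Bq/mL).
#' @param c_p blood activities per time point (Bq/mL).
#' @param c_p_integral blood-curve integrals per time point (Bq.min/mL).
#' @param k_h upper bound on x (from [hunter_k()]), >= 0.
#' @return list with `ki` (x), `vp` (y), `objective`, `degenerate`.
#' @export
solve_constrained <- function(c_fdg, c_p, c_p_integral, k_h) {
  assert_that(is_scalar_number(k_h) && k_h >= 0, "k_h must be a non-negative scalar")
  assert_that(length(c_fdg) >= 2, "at least 2 time points are required")
  stopifnot(length(c_p) == length(c_fdg), length(c_p_integral) == length(c_fdg))
  sol <- solve_constrained_batch(rbind(c_fdg), rbind(c_p), rbind(c_p_integral), k_h)
  list(ki = sol$x[1], vp = sol$y[1],
       objective = sol$f[1] + sum(c_fdg^2), degenerate = sol$degenerate[1])
}

#' Monte-Carlo Ki/Vp estimation under the measurement-error model
#'
#' Propagates the measurement-error model through the constrained solver:
#' each draw perturbs every tissue value by `N(0, var_fdg_k)` and the
#' blood values by `N(0, var_p)` — a single shared blood error across
#' time points in `"shared"` mode (counting-error model for blood
#' samples), independent per-time-point errors in `"per_timepoint"` mode
#' (IDIF error model). The blood integral is rescaled consistently with
#' the perturbed blood value (ratio perturbed/unperturbed per time
#' point). Negative perturbed activities are clipped at zero. The box
#' bound `K_H` is computed once from the unperturbed means. The estimate
#' is the mean (or median) of the per-draw solutions.
#'
#' @param meas a [measurement_set()].
#' @param n_draws number of random draws (>= 1).
#' @param seed integer seed; the draw stream is: tissue errors as
#'   `rnorm(n_draws * K)` filled column-major into an n x K matrix, then
#'   blood errors (same shape, or length n in shared mode).
#' @param sigma_p_mode `"per_timepoint"` or `"shared"`.
#' @param summary `"mean"` (default) or `"median"` of the draw solutions.
#' @return a `kinetic_estimate` with Monte-Carlo sd's; if all variances
#'   are zero the single deterministic constrained solution (sd 0).
#' @export
monte_carlo_estimate <- function(meas, n_draws = 10000L, seed = 1L,
                                 sigma_p_mode = c("per_timepoint", "shared"),
                                 summary = c("mean", "median")) {
  stopifnot(inherits(meas, "measurement_set"))
  sigma_p_mode <- match.arg(sigma_p_mode)
  summary <- match.arg(summary)
  assert_that(n_draws >= 1, "n_draws must be >= 1")
  K <- nrow(meas)
  kh <- hunter_k(meas)

  if (all(meas$c_fdg_var == 0) && all(meas$c_p_var == 0)) {
    sol <- solve_constrained(meas$c_fdg_mean, meas$c_p_mean, meas$c_p_integral, kh)
    return(kinetic_estimate(sol$ki, sol$vp, 0, 0, as.integer(n_draws),
                            as.integer(seed), kh, sol$degenerate))
  }

  sd_fdg <- sqrt(meas$c_fdg_var)
  draws <- with_seed(seed, {
    eps_fdg <- matrix(stats::rnorm(n_draws * K), n_draws, K)
    if (sigma_p_mode == "shared") {
      sd_p <- sqrt(mean(meas$c_p_var))
      eps_p <- matrix(stats::rnorm(n_draws) * sd_p, n_draws, K)
    } else {
      sd_p <- sqrt(meas$c_p_var)
      eps_p <- sweep(matrix(stats::rnorm(n_draws * K), n_draws, K), 2, sd_p, `*`)
    }
    list(fdg = sweep(eps_fdg, 2, sd_fdg, `*`), p = eps_p)
  })

  Cmat <- pmax(sweep(draws$fdg, 2, meas$c_fdg_mean, `+`), 0)
  Pmat <- pmax(sweep(draws$p, 2, meas$c_p_mean, `+`), 0)
  ratio <- sweep(Pmat, 2, pmax(meas$c_p_mean, .Machine$double.xmin), `/`)
  Imat <- sweep(ratio, 2, meas$c_p_integral, `*`)
  sol <- solve_constrained_batch(Cmat, Pmat, Imat, kh)

  stat <- if (summary == "mean") mean else stats::median
  kinetic_estimate(ki = stat(sol$x), vp = stat(sol$y),
                   ki_sd = stats::sd(sol$x), vp_sd = stats::sd(sol$y),
                   n_draws = as.integer(n_draws), seed = as.integer(seed),
                   k_h = kh, degenerate = any(sol$degenerate))
}

#' Three-slice maximum statistic of a lesion
#'
#' The lesion-level measurement: the lesion global maximum (located in
#' the time-averaged mean image) defines the central slice; in it and its
#' two neighbours the per-slice maximum position (within the lesion mask)
#' is located once and those three fixed voxel positions are read at
#' every time point. Per bin, the statistic is the mean of the three
#' values and their (n-1) sample variance.
#'
#' @param stats a [frame_statistics] object.
#' @param lesion_mask logical volume spanning >= 3 slices.
#' @return list with `positions` (3 x 3 voxel coordinates), `c_fdg_mean`
#'   and `c_fdg_var` (one value per bin).
#' @export
lesion_slice_statistics <- function(stats, lesion_mask) {
  stopifnot(inherits(stats, "frame_statistics"))
  avg <- Reduce(`+`, stats$mean_images) / length(stats$mean_images)
  zs <- sort(unique(which(lesion_mask, arr.ind = TRUE)[, 3]))
  assert_that(length(zs) >= 3, "lesion mask must span at least 3 slices")
  gmax <- which_max_voxel(avg, lesion_mask)
  z0 <- gmax$coord[3]
  z0 <- min(max(z0, zs[1] + 1L), zs[length(zs)] - 1L)
  slices <- (z0 - 1L):(z0 + 1L)
  pos <- lapply(slices, function(z) {
    mz <- lesion_mask[, , z]
    assert_that(any(mz), "a slice adjacent to the lesion maximum has no lesion voxels")
    ij <- arrayInd(which.max(ifelse(mz, avg[, , z], -Inf)), dim(mz))[1, ]
    c(ij, z)
  })
  pos <- do.call(rbind, pos)
  vals <- vapply(stats$mean_images, function(img) img[pos], numeric(nrow(pos)))
  list(positions = pos, c_fdg_mean = colMeans(vals),
       c_fdg_var = apply(vals, 2, stats::var))
}

#' Lesion-level Monte-Carlo estimator (3-slice maximum statistic)
#'
#' Whole-lesion Ki/Vp with measurement errors taken from the three
#' consecutive slices around the lesion maximum: per temporal bin, the
#' tissue value is the mean of the per-slice maxima over those three
#' slices (voxel positions fixed across bins) and its variance is their
#' (n-1) sample variance. Blood values come either from venous samples
#' (counting-CV variance, `blood` a [blood_samples()]) or from the IDIF
#' (`blood` an [idif_from_roi()] result); the blood error is shared
#' across time points (single draw per iteration). The population
#' input-function shape is rescaled to the blood data to supply the
#' integral term.
#'
#' @param stats a [frame_statistics] object.
#' @param lesion_mask logical volume spanning >= 3 slices.
#' @param blood a `blood_samples` or `idif` object.
#' @param input_fn a [triexp_input()] shape for the integral term.
#' @param n_draws,seed Monte-Carlo settings.
#' @return a `kinetic_estimate`.
#' @export
barbolosi_lesion <- function(stats, lesion_mask, blood,
                             input_fn = default_input_function(),
                             n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(stats, "frame_statistics"))
  lesion <- lesion_slice_statistics(stats, lesion_mask)
  t_k <- stats$bin_mid_times
  c_fdg_mean <- lesion$c_fdg_mean
  c_fdg_var <- lesion$c_fdg_var

  if (inherits(blood, "blood_samples")) {
    act <- stats::approx(blood$time_min, blood$activity_bq_ml, xout = t_k, rule = 2)$y
    cv <- mean(blood$counting_cv)
    c_p_mean <- act
    c_p_var <- rep((cv * mean(act))^2, length(t_k))
    scaled <- scale_to_samples(input_fn, blood$time_min, blood$activity_bq_ml)
  } else if (inherits(blood, "idif")) {
    c_p_mean <- blood$c_p_mean
    c_p_var <- blood$c_p_var
    scaled <- scale_to_samples(input_fn, blood$t, blood$c_p_mean)
  } else {
    stop("blood must be a blood_samples or idif object", call. = FALSE)
  }
  meas <- measurement_set(t_k, c_fdg_mean, c_fdg_var, c_p_mean, c_p_var,
                          integrate_cp(scaled, t_k))
  monte_carlo_estimate(meas, n_draws = n_draws, seed = seed, sigma_p_mode = "shared")
}

#' Voxel-level Monte-Carlo parametric mapping
#'
#' The voxel-level estimator: for every voxel in the mask, a measurement
#' set is assembled from that voxel's per-bin mean and variance, the IDIF
#' mean and per-time-point variance, and the (rescaled) input-function
#' integral; [monte_carlo_estimate()] is then run per voxel with
#' independent per-time-point blood errors. The voxel's own first-bin
#' values define its K_H bound. Per-voxel seeds are drawn once from the
#' master seed, so the map is bit-reproducible.
#'
#' @param stats a (realigned) [frame_statistics] object.
#' @param idif an [idif_from_roi()] result (one row per bin).
#' @param mask logical volume of voxels to map (non-empty).
#' @param input_fn a [triexp_input()] shape; rescaled to the IDIF means
#'   unless `scale_input` is `FALSE`.
#' @param n_draws draws per voxel (default 1000).
#' @param seed master integer seed.
#' @param summary `"mean"` or `"median"` per-draw summary.
#' @param scale_input rescale `input_fn` to the IDIF before integrating.
#' @return object of class `kinetic_map`: `ki_map`, `vp_map`,
#'   `ki_sd_map`, `vp_sd_map` (NA outside the mask), `mask`, `ki_max`,
#'   `vp_max` and their voxel coordinates, `n_draws`, `seed`.
#' @export
parapet_voxel <- function(stats, idif, mask, input_fn = default_input_function(),
                          n_draws = 1000L, seed = 1L,
                          summary = c("mean", "median"), scale_input = TRUE) {
  stopifnot(inherits(stats, "frame_statistics"), inherits(idif, "idif"))
  summary <- match.arg(summary)
  assert_that(any(mask), "mask is empty")
  assert_that(nrow(idif) == length(stats$mean_images),
              "idif must have one entry per temporal bin")
  t_k <- stats$bin_mid_times
  fn <- if (scale_input) scale_to_samples(input_fn, idif$t, idif$c_p_mean) else input_fn
  icp <- integrate_cp(fn, t_k)

  idx <- which(mask)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(idx)))
  d3 <- dim(mask)
  ki_map <- vp_map <- ki_sd_map <- vp_sd_map <- array(NA_real_, d3)

  mean_mat <- vapply(stats$mean_images, function(img) img[idx], numeric(length(idx)))
  var_mat <- vapply(stats$var_images, function(img) img[idx], numeric(length(idx)))

  for (j in seq_along(idx)) {
    meas <- measurement_set(t_k, mean_mat[j, ], var_mat[j, ],
                            idif$c_p_mean, idif$c_p_var, icp)
    est <- monte_carlo_estimate(meas, n_draws = n_draws, seed = seeds[j],
                                sigma_p_mode = "per_timepoint", summary = summary)
    ki_map[idx[j]] <- est$ki
    vp_map[idx[j]] <- est$vp
    ki_sd_map[idx[j]] <- est$ki_sd
    vp_sd_map[idx[j]] <- est$vp_sd
  }

  ki_max <- which_max_voxel(ki_map, mask)
  vp_max <- which_max_voxel(vp_map, mask)
  structure(list(ki_map = ki_map, vp_map = vp_map,
                 ki_sd_map = ki_sd_map, vp_sd_map = vp_sd_map, mask = mask,
                 ki_max = ki_max$value, ki_max_coord = ki_max$coord,
                 vp_max = vp_max$value, vp_max_coord = vp_max$coord,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "kinetic_map")
}

#' @export
print.kinetic_map <- function(x, ...) {
  cat(sprintf("Kinetic map over %d voxels: Ki_max = %.5g at (%s), Vp_max = %.4g at (%s)\n",
              sum(x$mask), x$ki_max, paste(x$ki_max_coord, collapse = ","),
              x$vp_max, paste(x$vp_max_coord, collapse = ",")))
  cat(sprintf("  %d draws per voxel, master seed %d\n", x$n_draws, x$seed))
  invisible(x)
}

#' Standardized uptake value image
#'
#' `SUV = activity / (injected dose / body weight)`, g/mL.
#'
#' @param frame activity volume (Bq/mL).
#' @param injected_dose injected activity (Bq), > 0.
#' @param body_weight body weight (g), > 0.
#' @return SUV volume (same shape as `frame`).
#' @export
suv_image <- function(frame, injected_dose, body_weight) {
  assert_that(is_scalar_number(injected_dose) && injected_dose > 0,
              "injected_dose must be a positive scalar (Bq)")
  assert_that(is_scalar_number(body_weight) && body_weight > 0,
              "body_weight must be a positive scalar (g)")
  frame / (injected_dose / body_weight)
}

#' Maximum of an image within a mask
#' @param image numeric volume.
#' @param mask logical volume (default: whole image).
#' @return list with `value`, `coord` (1-based voxel coordinates).
#' @export
map_max <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  assert_that(any(mask), "mask is empty")
  which_max_voxel(image, mask)[c("value", "coord")]
}
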