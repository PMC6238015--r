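# Blood input function: tri-exponential model, scaling, fitting, and the
# image-derived input function (IDIF) extracted from an aorta ROI.

#' Tri-exponential blood input-function model
#'
#' FDG blood activity concentration is modelled as a sum of three decaying
#' exponentials, `Cp(t) = sum_j A_j exp(-lambda_j (t - t0))`, the classical
#' population shape for the late FDG blood curve. The shape is typically
#' taken from a population template and rescaled to one or more measured
#' blood values ([scale_to_sample()]) or fitted to data ([fit_triexp()]).
#'
#' @param A numeric vector of 3 amplitudes (Bq/mL). Must be finite and
#'   non-negative (guaranteeing `Cp(t) >= 0`).
#' @param lambda numeric vector of 3 decay rates (1/min), all > 0.
#' @param t0 injection time offset (min); the model is defined for
#'   `t >= t0`.
#' @return An object of class `triexp_input`.
#' @examples
#' cp <- triexp_input(A = c(1000, 0, 0), lambda = c(0.1, 1, 1))
#' evaluate_cp(cp, 10)  # 1000 * exp(-1)
#' @export
triexp_input <- function(A, lambda, t0 = 0) {
  assert_that(length(A) == 3L && all(is.finite(A)), "A must be 3 finite amplitudes")
  assert_that(all(A >= 0), "amplitudes must be non-negative")
  assert_that(length(lambda) == 3L && all(is.finite(lambda)) && all(lambda > 0),
              "lambda must be 3 positive decay rates")
  assert_that(is_scalar_number(t0), "t0 must be a finite scalar")
  structure(list(A = as.numeric(A), lambda = as.numeric(lambda), t0 = as.numeric(t0)),
            class = "triexp_input")
}

#' @export
print.triexp_input <- function(x, ...) {
  cat("Tri-exponential input function\n")
  cat(sprintf("  A      = %s  (Bq/mL)\n", paste(signif(x$A, 5), collapse = ", ")))
  cat(sprintf("  lambda = %s  (1/min)\n", paste(signif(x$lambda, 5), collapse = ", ")))
  cat(sprintf("  t0     = %g min\n", x$t0))
  invisible(x)
}

#' Default population input-function shape
#'
#' A synthetic population tri-exponential shipped as the package default.
#' These coefficients are not from any publication; they were chosen to
#' give a realistic bolus peak and a late (80--95 min) blood activity of
#' roughly 1.5 kBq/mL, and are intended to be rescaled to each subject's
#' blood data before quantitative use.
#' @return A `triexp_input`.
#' @export
default_input_function <- function() {
  triexp_input(A = c(90000, 18000, 3300), lambda = c(3.0, 0.3, 0.009), t0 = 0)
}

#' Evaluate the blood curve Cp(t)
#'
#' @param model a [triexp_input()].
#' @param t times (min post-injection), all `>= t0`.
#' @return activity concentration (Bq/mL), same length as `t`.
#' @export
evaluate_cp <- function(model, t) {
  stopifnot(inherits(model, "triexp_input"))
  assert_that(all(t >= model$t0), "t must be >= t0 (model undefined before injection)")
  tt <- outer(t - model$t0, model$lambda)
  as.numeric(exp(-tt) %*% model$A)
}

#' Integral of the blood curve from injection to t
#'
#' Closed-form antiderivative `sum_j (A_j/lambda_j)(1 - exp(-lambda_j (t - t0)))`,
#' in Bq.min/mL; monotone non-decreasing in `t`.
#' @inheritParams evaluate_cp
#' @export
integrate_cp <- function(model, t) {
  stopifnot(inherits(model, "triexp_input"))
  assert_that(all(t >= model$t0), "t must be >= t0 (model undefined before injection)")
  tt <- outer(t - model$t0, model$lambda)
  as.numeric((1 - exp(-tt)) %*% (model$A / model$lambda))
}

#' Rescale the input-function shape to a measured blood sample
#'
#' Multiplies all amplitudes by `measured / Cp(t_s)` so the scaled curve
#' passes exactly through the measured value, preserving the population
#' shape. This is the single-sample calibration used by single-time-point
#' Ki estimation.
#'
#' @param model a [triexp_input()].
#' @param t_s sample time (min).
#' @param measured measured blood activity at `t_s` (Bq/mL).
#' @return the rescaled `triexp_input`.
#' @export
scale_to_sample <- function(model, t_s, measured) {
  assert_that(is_scalar_number(t_s) && is_scalar_number(measured),
              "t_s and measured must be finite scalars")
  cur <- evaluate_cp(model, t_s)
  assert_that(cur > 0, "model evaluates to zero at t_s; cannot scale")
  triexp_input(model$A * (measured / cur), model$lambda, model$t0)
}

#' Least-squares amplitude rescaling to several blood values
#'
#' Single multiplicative factor minimizing the sum of squared differences
#' between the scaled curve and the measured values (factor =
#' sum(m*cp)/sum(cp^2)). Used to anchor a population shape to 4--5 late
#' samples or to the IDIF.
#' @param model a [triexp_input()].
#' @param times sample times (min).
#' @param values measured activities (Bq/mL).
#' @return the rescaled `triexp_input`.
#' @export
scale_to_samples <- function(model, times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  cp <- evaluate_cp(model, times)
  denom <- sum(cp^2)
  assert_that(denom > 0, "model is zero at all sample times; cannot scale")
  f <- sum(values * cp) / denom
  assert_that(f >= 0, "negative scale factor; blood values inconsistent with shape")
  triexp_input(model$A * f, model$lambda, model$t0)
}

#' Fit a tri-exponential input function to blood data
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of
#' the tri-exponential model to measured blood activities, e.g. an early
#' dynamic heart acquisition combined with late venous samples. Multiple
#' randomized starts are attempted and the best fit is kept; decay rates
#' are constrained positive and amplitudes non-negative.
#'
#' @param times sample times (min), at least 6 points spanning early and
#'   late phases.
#' @param values measured activities (Bq/mL).
#' @param seed integer seed for the randomized multistart.
#' @param n_starts number of randomized starts.
#' @param t0 fixed injection offset (min).
#' @return a fitted `triexp_input` whose residual norm is no worse than
#'   the best initialization's.
#' @export
fit_triexp <- function(times, values, seed = 1L, n_starts = 20L, t0 = 0) {
  assert_that(length(times) == length(values), "times and values must have equal length")
  assert_that(length(times) >= 6L, "at least 6 points are required to fit 6 parameters")
  assert_that(all(times >= t0), "all times must be >= t0")
  ord <- order(times)
  times <- as.numeric(times[ord]); values <- as.numeric(values[ord])
  peak <- max(values)

  make_start <- function(jitter) {
    lam <- c(2, 0.2, 0.01) * exp(jitter * stats::rnorm(3, sd = 0.5))
    amp <- pmax(peak * c(1, 0.3, 0.1) * exp(jitter * stats::rnorm(3, sd = 0.5)), 1e-6)
    list(A1 = amp[1], A2 = amp[2], A3 = amp[3],
         l1 = lam[1], l2 = lam[2], l3 = lam[3])
  }
  rss_of <- function(p) {
    pred <- p[["A1"]] * exp(-p[["l1"]] * (times - t0)) +
      p[["A2"]] * exp(-p[["l2"]] * (times - t0)) +
      p[["A3"]] * exp(-p[["l3"]] * (times - t0))
    sum((values - pred)^2)
  }

  best <- NULL
  best_rss <- Inf
  init_rss <- Inf
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- make_start(jitter = as.numeric(s > 1))
      init_rss <- min(init_rss, rss_of(start))
      fit <- try(minpack.lm::nlsLM(
        v ~ A1 * exp(-l1 * (t - t0)) + A2 * exp(-l2 * (t - t0)) + A3 * exp(-l3 * (t - t0)),
        data = data.frame(t = times, v = values, t0 = t0),
        start = start,
        lower = c(A1 = 0, A2 = 0, A3 = 0, l1 = 1e-6, l2 = 1e-6, l3 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        p <- as.list(stats::coef(fit))
        rss <- rss_of(p)
        if (rss < best_rss) {
          best_rss <- rss
          best <- p
        }
      }
    }
  })
  if (is.null(best) || best_rss > init_rss + 1e-8) {
    e <- simpleError("tri-exponential fit did not converge below its initialization")
    e$best_so_far <- best
    stop(e)
  }
  ord_l <- order(c(best$l1, best$l2, best$l3), decreasing = TRUE)
  triexp_input(c(best$A1, best$A2, best$A3)[ord_l],
               c(best$l1, best$l2, best$l3)[ord_l], t0)
}

#' Venous blood sample table
#'
#' Container for the 4--5 late venous samples used by the blood-sample
#' estimator variants, with the gamma-counter counting coefficient of
#' variation attached.
#'
#' @param times sample times (min post-injection), strictly increasing.
#' @param activities whole-blood activity (Bq/mL), non-negative.
#' @param counting_cv counting coefficient of variation (fraction), a
#'   scalar or one value per sample.
#' @return object of class `blood_samples` (a data frame).
#' @export
blood_samples <- function(times, activities, counting_cv = 0.02) {
  assert_that(length(times) == length(activities), "times/activities length mismatch")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(all(activities >= 0), "activities must be non-negative")
  cv <- rep_len(counting_cv, length(times))
  assert_that(all(cv >= 0), "counting_cv must be non-negative")
  structure(data.frame(time_min = as.numeric(times),
                       activity_bq_ml = as.numeric(activities),
                       counting_cv = cv),
            class = c("blood_samples", "data.frame"))
}

#' Read/write blood samples as CSV
#'
#' CSV columns: `time_min, activity_bq_ml, counting_cv`.
#' @param path file path.
#' @return `read_blood_samples` returns a [blood_samples()] object.
#' @export
read_blood_samples <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_min", "activity_bq_ml", "counting_cv")
  assert_that(all(need %in% names(d)),
              sprintf("blood sample CSV must have columns: %s", paste(need, collapse = ", ")))
  blood_samples(d$time_min, d$activity_bq_ml, d$counting_cv)
}

#' @rdname read_blood_samples
#' @param samples a [blood_samples()] object.
#' @export
write_blood_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Image-derived input function from an aorta ROI
#'
#' Extracts the blood curve from the frame statistics: for each temporal
#' bin, the mean IDIF value is the ROI average of the bin's mean image,
#' and the IDIF variance is the (n-1) sample variance of the ROI means of
#' the bin's overlapping-window reconstructions — i.e. the variability of
#' the blood measurement itself, not the spatial variance across the ROI.
#'
#' @param stats a [frame_statistics] object (see [mean_variance_images()]).
#' @param aorta_mask logical volume on the same grid, non-empty.
#' @return data frame of class `idif`: `t` (min), `c_p_mean` (Bq/mL),
#'   `c_p_var` (Bq^2/mL^2), one row per bin.
#' @export
idif_from_roi <- function(stats, aorta_mask) {
  stopifnot(inherits(stats, "frame_statistics"))
  assert_that(any(aorta_mask), "aorta mask is empty")
  assert_that(all(dim(aorta_mask) == dim(stats$mean_images[[1]])),
              "aorta mask is not on the frame-statistics grid")
  idx <- which(aorta_mask)
  n_bins <- length(stats$mean_images)
  cp_mean <- vapply(stats$mean_images, function(v) mean(v[idx]), 0)
  cp_var <- vapply(seq_len(n_bins), function(b) {
    wm <- vapply(stats$window_images[[b]], function(v) mean(v[idx]), 0)
    stats::var(wm)
  }, 0)
  structure(data.frame(t = stats$bin_mid_times, c_p_mean = cp_mean, c_p_var = cp_var),
            class = c("idif", "data.frame"))
}
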