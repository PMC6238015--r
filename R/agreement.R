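# Method-agreement machinery: Bland-Altman ratios, ICC, Wilcoxon paired
# tests, Pearson correlation, response deltas, convergence-vs-draws
# analysis and lesion/necrosis contrast.

#' Paired measurements from two methods
#'
#' @param method_values,reference_values equal-length numeric vectors.
#' @param labels optional case labels.
#' @return object of class `paired_measurements` (a data frame).
#' @export
paired_measurements <- function(method_values, reference_values, labels = NULL) {
  n <- length(method_values)
  assert_that(length(reference_values) == n, "columns must have equal length")
  labels <- labels %||% as.character(seq_len(n))
  structure(data.frame(label = labels, method = as.numeric(method_values),
                       reference = as.numeric(reference_values)),
            class = c("paired_measurements", "data.frame"))
}

as_pairs <- function(pairs) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  if (is.matrix(pairs) && ncol(pairs) == 2) {
    return(paired_measurements(pairs[, 1], pairs[, 2]))
  }
  stop("expected a paired_measurements object or a 2-column matrix", call. = FALSE)
}

#' Bland-Altman ratio agreement
#'
#' Ratios `r_i = method_i / reference_i`; the 95% limits of agreement are
#' `mean(r) +/- 1.96 sd(r)` and are also expressed as a percentage of the
#' mean ratio (`1.96 sd / mean * 100`), the usual summary for
#' method-comparison on a multiplicative scale.
#'
#' @param pairs a [paired_measurements()] (references must be > 0).
#' @return list with `mean_ratio`, `loa_low`, `loa_high`, `loa_pct`,
#'   `ratios`.
#' @export
bland_altman_ratio <- function(pairs) {
  pairs <- as_pairs(pairs)
  assert_that(nrow(pairs) >= 3, "at least 3 pairs are required for limits of agreement")
  assert_that(all(pairs$reference > 0), "reference values must be strictly positive")
  r <- pairs$method / pairs$reference
  m <- mean(r)
  s <- stats::sd(r)
  list(mean_ratio = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       loa_pct = 1.96 * s / m * 100, ratios = r)
}

#' Intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(2,1)) from the mean-squares decomposition: with n subjects and k
#' raters, `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Consistency (ICC(3,1)) and one-way (ICC(1,1)) forms are also exposed.
#'
#' @param pairs a [paired_measurements()] (k = 2 raters) or an n x k
#'   numeric matrix.
#' @param type `"ICC2"` (default, absolute agreement), `"ICC3"`
#'   (consistency) or `"ICC1"` (one-way).
#' @return scalar ICC in [-1, 1].
#' @export
icc <- function(pairs, type = c("ICC2", "ICC3", "ICC1")) {
  type <- match.arg(type)
  m <- if (inherits(pairs, "paired_measurements")) {
    cbind(pairs$method, pairs$reference)
  } else {
    as.matrix(pairs)
  }
  n <- nrow(m)
  k <- ncol(m)
  assert_that(n >= 3, "at least 3 subjects are required")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msw <- (ss_cols + ss_err) / (n * (k - 1))
  switch(type,
         ICC2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         ICC3 = (msr - mse) / (msr + (k - 1) * mse),
         ICC1 = (msr - msw) / (msr + (k - 1) * msw))
}

#' Wilcoxon paired signed-rank test
#'
#' Paired signed-rank test of method vs reference, exact for n <= 25
#' without ties or zero differences, normal approximation (with
#' continuity correction) otherwise.
#'
#' @param pairs a [paired_measurements()].
#' @param alternative `"two_sided"`, `"greater"` (method > reference) or
#'   `"less"`.
#' @return p value.
#' @export
wilcoxon_paired <- function(pairs, alternative = c("two_sided", "greater", "less")) {
  pairs <- as_pairs(pairs)
  alternative <- match.arg(alternative)
  d <- pairs$method - pairs$reference
  assert_that(any(d != 0), "all paired differences are zero; the statistic is undefined")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  n_nonzero <- sum(d != 0)
  has_ties <- anyDuplicated(abs(d[d != 0])) > 0
  exact <- n_nonzero <= 25 && !has_ties && all(d != 0)
  suppressWarnings(
    stats::wilcox.test(pairs$method, pairs$reference, paired = TRUE,
                       alternative = alt, exact = exact, correct = TRUE)$p.value
  )
}

#' Pearson correlation with significance
#'
#' @param pairs a [paired_measurements()].
#' @return list with `r` and the t-distribution `p` value.
#' @export
pearson <- function(pairs) {
  pairs <- as_pairs(pairs)
  assert_that(stats::sd(pairs$method) > 0 && stats::sd(pairs$reference) > 0,
              "a column has zero variance; correlation is undefined")
  ct <- stats::cor.test(pairs$method, pairs$reference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fractional treatment-response deltas
#'
#' `delta = (followup - baseline) / baseline` for the lesion maxima of a
#' kinetic map and an SUV image. With `same_voxel = TRUE` (default) the
#' follow-up value is read at the voxel of the baseline maximum, so both
#' time points refer to the same tissue position; otherwise each scan's
#' own maximum is used.
#'
#' @param baseline,followup lists with elements `ki` (a `kinetic_map` or
#'   numeric volume), `suv` (numeric volume) and `mask` (logical volume).
#' @param same_voxel logical voxel-matching policy.
#' @return list with `delta_ki_max` and `delta_suv_max` (unitless).
#' @export
delta_response <- function(baseline, followup, same_voxel = TRUE) {
  get_map <- function(x) if (inherits(x, "kinetic_map")) x$ki_map else x
  delta_of <- function(img0, img1, mask) {
    m0 <- which_max_voxel(img0, mask)
    assert_that(is.finite(m0$value) && m0$value != 0, "baseline maximum is zero")
    v1 <- if (same_voxel) img1[m0$index] else which_max_voxel(img1, mask)$value
    (v1 - m0$value) / m0$value
  }
  list(delta_ki_max = delta_of(get_map(baseline$ki), get_map(followup$ki), baseline$mask),
       delta_suv_max = delta_of(baseline$suv, followup$suv, baseline$mask))
}

#' Monte-Carlo convergence versus number of draws
#'
#' Repeats [monte_carlo_estimate()] `repeats` times (distinct seeds) at
#' each draw count and summarizes the run-to-run spread of the Ki and Vp
#' estimates as a coefficient of variation (sd/mean over the repeats).
#' Because the estimate is a mean over draws, its CV falls approximately
#' as 1/sqrt(n).
#'
#' @param meas a [measurement_set()].
#' @param draws_list draw counts to evaluate.
#' @param repeats repeated estimations per draw count (>= 2).
#' @param seed master seed; per-run seeds are derived from it.
#' @param sigma_p_mode passed to [monte_carlo_estimate()].
#' @return data frame: `n_draws`, `ki_mean`, `ki_cv`, `vp_mean`, `vp_cv`
#'   (CVs as fractions).
#' @export
convergence_analysis <- function(meas, draws_list = c(10, 100, 1000, 10000),
                                 repeats = 5L, seed = 1L,
                                 sigma_p_mode = "per_timepoint") {
  stopifnot(inherits(meas, "measurement_set"))
  assert_that(repeats >= 2, "at least 2 repeats are required for a CV")
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             length(draws_list) * repeats),
                                  length(draws_list), repeats))
  out <- lapply(seq_along(draws_list), function(i) {
    ests <- lapply(seq_len(repeats), function(r) {
      monte_carlo_estimate(meas, n_draws = draws_list[i], seed = seeds[i, r],
                           sigma_p_mode = sigma_p_mode)
    })
    ki <- vapply(ests, `[[`, 0, "ki")
    vp <- vapply(ests, `[[`, 0, "vp")
    cv <- function(x) if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
    data.frame(n_draws = draws_list[i], ki_mean = mean(ki), ki_cv = cv(ki),
               vp_mean = mean(vp), vp_cv = cv(vp))
  })
  do.call(rbind, out)
}

#' Lesion-to-necrosis contrast ratio
#'
#' Maximum over the lesion mask divided by the mean over the necrotic
#' mask; scale-invariant.
#'
#' @param image numeric volume (e.g. an SUV or Ki image).
#' @param lesion_mask,necrotic_mask logical volumes.
#' @return scalar contrast ratio.
#' @export
contrast_ratio <- function(image, lesion_mask, necrotic_mask) {
  assert_that(any(lesion_mask), "lesion mask is empty")
  assert_that(any(necrotic_mask), "necrotic mask is empty")
  nec_mean <- mean(image[necrotic_mask])
  assert_that(nec_mean != 0, "necrotic mean is zero; contrast undefined")
  max(image[lesion_mask]) / nec_mean
}

#' Normalize an image for cross-modality comparison
#'
#' Either divides every slice by its total counts (`"slice_counts"`) or
#' the whole image by the mean over a background mask (`"background"`),
#' the two conventions used when overlaying SUV and Ki images.
#'
#' @param image numeric volume.
#' @param mode `"slice_counts"` or `"background"`.
#' @param background_mask logical volume (required for `"background"`).
#' @return the normalized volume.
#' @export
normalize_image <- function(image, mode = c("slice_counts", "background"),
                            background_mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "slice_counts") {
    out <- image
    for (z in seq_len(dim(image)[3])) {
      tot <- sum(image[, , z])
      if (tot != 0) out[, , z] <- image[, , z] / tot
    }
    out
  } else {
    assert_that(!is.null(background_mask) && any(background_mask),
                "background mode requires a non-empty background_mask")
    bg <- mean(image[background_mask])
    assert_that(bg != 0, "background mean is zero")
    image / bg
  }
}
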