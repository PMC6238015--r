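# Overlapping-window rebinning of the late 15-min acquisition into
# per-bin mean and variance images, and mutual-information rigid
# realignment of the five temporal bins onto the central one.

#' Rebin a fine series into overlapping reconstruction windows
#'
#' Emulates retrospective listmode rebinning: the acquisition is split
#' into `n_bins` bins of `bin_len` minutes, and within each bin
#' `n_windows` overlapping windows of `window_len` minutes are formed,
#' staggered by `offset` minutes. At the defaults (3-min bins, five 2-min
#' windows offset by 15 s) a 15-min series yields 25 window images; the
#' first bin's windows cover 0-2, 0:15-2:15, 0:30-2:30, 0:45-2:45 and
#' 1-3 min of the acquisition. Each window image is the duration-weighted
#' mean of the subframes it covers.
#'
#' @param series a [dynamic_series()] on a uniform fine subframe grid.
#' @param bin_len bin length (min).
#' @param window_len window length (min).
#' @param offset stagger between successive windows (min); must be a
#'   multiple of the subframe length.
#' @param n_windows windows per bin.
#' @param n_bins number of bins; default `floor(span / bin_len)`.
#' @return object of class `window_set`: per bin, the window images and
#'   window mid-times; plus bin mid-times (min post-injection).
#' @export
rebin_overlapping <- function(series, bin_len = 3, window_len = 2, offset = 0.25,
                              n_windows = 5L, n_bins = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  starts <- series$frame_starts
  ends <- series$frame_ends
  tau <- ends - starts
  assert_that(max(abs(tau - tau[1])) < 1e-9, "subframes must have uniform length")
  tau <- tau[1]
  assert_that(abs(offset / tau - round(offset / tau)) < 1e-9,
              "offset must be a multiple of the subframe length")
  span <- ends[length(ends)] - starts[1]
  n_bins <- n_bins %||% floor(span / bin_len + 1e-9)
  assert_that(n_bins >= 1, "series too short for a single bin")
  assert_that(span + 1e-9 >= n_bins * bin_len, "series too short for the requested bins")
  assert_that((n_windows - 1) * offset + window_len <= bin_len + 1e-9,
              "windows extend past their bin")

  rel_start <- starts - starts[1]
  rel_end <- ends - starts[1]
  d3 <- dim(series$frames)[1:3]
  bins <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    wins <- vector("list", n_windows)
    mids <- numeric(n_windows)
    for (w in seq_len(n_windows)) {
      w0 <- (b - 1) * bin_len + (w - 1) * offset
      w1 <- w0 + window_len
      sel <- which(rel_start >= w0 - 1e-9 & rel_end <= w1 + 1e-9)
      assert_that(length(sel) >= 1, "window covers no subframes")
      img <- array(0, d3)
      for (k in sel) img <- img + series$frames[, , , k]
      wins[[w]] <- img / length(sel)
      mids[w] <- starts[1] + (w0 + w1) / 2
    }
    bins[[b]] <- list(windows = wins, window_mid_times = mids)
  }
  structure(list(bins = bins,
                 bin_mid_times = starts[1] + bin_len * (seq_len(n_bins) - 0.5),
                 n_windows = n_windows,
                 voxel_size = series$voxel_size),
            class = "window_set")
}

#' Per-bin mean and variance images
#'
#' Voxelwise mean and unbiased (n-1) sample variance over each bin's
#' overlapping window images. These are the measured activity and its
#' measurement-error variance entering the Monte-Carlo estimators. The
#' overlapping windows share data, so the sample variance is a
#' bootstrap-like surrogate rather than an independent-replicate
#' estimate; it is used as-is by design.
#'
#' @param windows a [rebin_overlapping()] result.
#' @return object of class `frame_statistics` with `mean_images`,
#'   `var_images` (lists of 3D arrays), `bin_mid_times`, and the retained
#'   `window_images` (list of lists) needed for the IDIF variance.
#' @export
mean_variance_images <- function(windows) {
  stopifnot(inherits(windows, "window_set"))
  n_bins <- length(windows$bins)
  mean_images <- vector("list", n_bins)
  var_images <- vector("list", n_bins)
  window_images <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    wins <- windows$bins[[b]]$windows
    n <- length(wins)
    assert_that(n >= 2, "at least 2 windows per bin are required for a variance")
    m <- Reduce(`+`, wins) / n
    ss <- Reduce(`+`, lapply(wins, function(w) (w - m)^2))
    mean_images[[b]] <- m
    var_images[[b]] <- pmax(ss / (n - 1), 0)
    window_images[[b]] <- wins
  }
  structure(list(mean_images = mean_images, var_images = var_images,
                 bin_mid_times = windows$bin_mid_times,
                 window_images = window_images,
                 voxel_size = windows$voxel_size),
            class = "frame_statistics")
}

#' @export
print.frame_statistics <- function(x, ...) {
  cat(sprintf("Frame statistics: %d bins x %d windows, bin mid-times %s min\n",
              length(x$mean_images), length(x$window_images[[1]]),
              paste(sprintf("%.1f", x$bin_mid_times), collapse = ", ")))
  invisible(x)
}

#' One-call frame statistics from a series
#' @inheritParams rebin_overlapping
#' @return a `frame_statistics` object.
#' @export
frame_statistics <- function(series, bin_len = 3, window_len = 2, offset = 0.25,
                             n_windows = 5L, n_bins = NULL) {
  mean_variance_images(rebin_overlapping(series, bin_len, window_len, offset,
                                         n_windows, n_bins))
}

# Translation maximizing MI(ref, translate(moving, s)): coarse integer
# grid then optional Nelder-Mead refinement with trilinear resampling.
estimate_translation <- function(ref, moving, max_shift = 3L, n_bins = 32L,
                                 refine = TRUE) {
  grid <- -max_shift:max_shift
  best <- c(0, 0, 0)
  best_mi <- -Inf
  for (sx in grid) for (sy in grid) for (sz in grid) {
    mi <- mutual_information(ref, shift_int(moving, c(sx, sy, sz)), n_bins)
    if (mi > best_mi) {
      best_mi <- mi
      best <- c(sx, sy, sz)
    }
  }
  if (refine) {
    obj <- function(s) -mutual_information(ref, translate_volume(moving, s), n_bins)
    opt <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-6))
    if (-opt$value > best_mi) {
      best <- opt$par
      best_mi <- -opt$value
    }
  }
  list(shift = best, mi = best_mi)
}

#' Realign frame statistics onto the central temporal bin
#'
#' Rigid (translation) realignment of each temporal bin onto the
#' reference bin (the central one, k = 3 of 5, by default), using a
#' 32-bin histogram mutual-information metric: a coarse integer-voxel
#' grid search followed by a local simplex refinement with trilinear
#' resampling. The estimated transform is applied to the bin's window
#' images and the per-bin statistics are recomputed from the realigned
#' windows. If a bin's optimized transform does not improve mutual
#' information with the reference over the identity, the identity is kept.
#'
#' @param stats a [frame_statistics] object.
#' @param ref_bin 1-based index of the reference bin (default: central).
#' @param max_shift integer search radius (voxels).
#' @param refine logical; run sub-voxel simplex refinement.
#' @return list with `stats` (realigned `frame_statistics`), `transforms`
#'   (n_bins x 3 voxel shifts applied), and `mi_before` / `mi_after`
#'   (per-bin mutual information with the reference mean image).
#' @export
register_to_central <- function(stats, ref_bin = NULL, max_shift = 3L, refine = TRUE) {
  stopifnot(inherits(stats, "frame_statistics"))
  n_bins <- length(stats$mean_images)
  ref_bin <- ref_bin %||% ((n_bins + 1L) %/% 2L)
  assert_that(ref_bin >= 1 && ref_bin <= n_bins, "ref_bin out of range")
  ref <- stats$mean_images[[ref_bin]]

  transforms <- matrix(0, n_bins, 3,
                       dimnames = list(NULL, c("dx_vox", "dy_vox", "dz_vox")))
  mi_before <- mi_after <- numeric(n_bins)
  window_images <- stats$window_images
  for (b in seq_len(n_bins)) {
    mi_before[b] <- mutual_information(ref, stats$mean_images[[b]])
    if (b == ref_bin) {
      mi_after[b] <- mi_before[b]
      next
    }
    est <- estimate_translation(ref, stats$mean_images[[b]], max_shift, refine = refine)
    realigned_mean <- translate_volume(stats$mean_images[[b]], est$shift)
    mi_new <- mutual_information(ref, realigned_mean)
    if (mi_new < mi_before[b]) {
      # identity guard: never leave a bin worse-aligned than it started
      transforms[b, ] <- 0
      mi_after[b] <- mi_before[b]
      next
    }
    transforms[b, ] <- est$shift
    mi_after[b] <- mi_new
    window_images[[b]] <- lapply(window_images[[b]],
                                 function(w) translate_volume(w, est$shift))
  }

  # recompute statistics from the realigned windows
  mean_images <- stats$mean_images
  var_images <- stats$var_images
  for (b in seq_len(n_bins)) {
    if (all(transforms[b, ] == 0)) next
    wins <- window_images[[b]]
    n <- length(wins)
    m <- Reduce(`+`, wins) / n
    ss <- Reduce(`+`, lapply(wins, function(w) (w - m)^2))
    mean_images[[b]] <- m
    var_images[[b]] <- pmax(ss / (n - 1), 0)
  }
  realigned <- structure(list(mean_images = mean_images, var_images = var_images,
                              bin_mid_times = stats$bin_mid_times,
                              window_images = window_images,
                              voxel_size = stats$voxel_size),
                         class = "frame_statistics")
  list(stats = realigned, transforms = transforms,
       mi_before = mi_before, mi_after = mi_after, ref_bin = ref_bin)
}
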