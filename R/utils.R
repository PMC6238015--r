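# Internal helpers: seeded evaluation, 3D array manipulation, mutual information.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions do not clobber the
#' global random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Voxel-centre sphere mask
#'
#' Logical 3D array marking voxels whose centre lies within `radius`
#' (voxel units) of `center` (1-based voxel coordinates).
#' @keywords internal
#' @noRd
sphere_mask <- function(shape, center, radius) {
  stopifnot(length(shape) == 3L, length(center) == 3L)
  dx <- (seq_len(shape[1]) - center[1])^2
  dy <- (seq_len(shape[2]) - center[2])^2
  dz <- (seq_len(shape[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, `+`), dz, `+`)
  d2 <= radius^2
}

cylinder_mask_z <- function(shape, center_xy, radius) {
  dx <- (seq_len(shape[1]) - center_xy[1])^2
  dy <- (seq_len(shape[2]) - center_xy[2])^2
  d2 <- outer(dx, dy, `+`)
  array(rep(d2 <= radius^2, shape[3]), dim = shape)
}

#' Coordinates (1-based) of the maximum of a volume, optionally masked
#' @keywords internal
#' @noRd
which_max_voxel <- function(vol, mask = NULL) {
  v <- vol
  if (!is.null(mask)) v[!mask] <- -Inf
  i <- which.max(v)
  coord <- arrayInd(i, dim(vol))[1, ]
  list(value = vol[i], coord = as.integer(coord), index = i)
}

#' Integer-voxel translation with zero fill
#'
#' out[i] = vol[i - s]: the image content moves by +s voxels.
#' @keywords internal
#' @noRd
shift_int <- function(vol, s) {
  d <- dim(vol)
  s <- as.integer(round(s))
  out <- array(0, d)
  rng <- lapply(1:3, function(a) {
    dst <- max(1L, 1L + s[a]):min(d[a], d[a] + s[a])
    if (max(1L, 1L + s[a]) > min(d[a], d[a] + s[a])) integer(0) else dst
  })
  if (any(vapply(rng, length, 1L) == 0L)) return(out)
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]] - s[1], rng[[2]] - s[2], rng[[3]] - s[3]]
  out
}

#' Trilinear sub-voxel translation with zero fill
#'
#' Translates a 3D volume by a continuous voxel shift. Content moves by
#' +shift; regions moved in from outside the field of view are zero.
#' @keywords internal
#' @noRd
translate_volume <- function(vol, shift) {
  stopifnot(length(shift) == 3L)
  base <- floor(shift)
  frac <- shift - base
  if (all(abs(frac) < 1e-12)) return(shift_int(vol, base))
  out <- array(0, dim(vol))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    c3 <- c(cx, cy, cz)
    w <- prod(ifelse(c3 == 1, frac, 1 - frac))
    if (w > 0) out <- out + w * shift_int(vol, base + c3)
  }
  out
}

#' Histogram mutual information between two equally-shaped volumes
#'
#' Shannon mutual information (nats) of the joint intensity histogram,
#' `n_bins` equal-width bins per image over each image's own range.
#' @param a,b numeric arrays of identical dimension.
#' @param n_bins number of histogram bins per image.
#' @return scalar mutual information in nats.
#' @export
mutual_information <- function(a, b, n_bins = 32L) {
  stopifnot(length(a) == length(b))
  bin_index <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    i <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
    pmin.int(i, n_bins)
  }
  ia <- bin_index(as.numeric(a))
  ib <- bin_index(as.numeric(b))
  joint <- tabulate((ib - 1L) * n_bins + ia, nbins = n_bins * n_bins)
  p <- joint / sum(joint)
  pm <- matrix(p, n_bins, n_bins)
  pa <- rowSums(pm)
  pb <- colSums(pm)
  pij <- outer(pa, pb)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / pij[nz]))
}
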