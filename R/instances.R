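#' Separate a foreground mask into glomerulus instances
#'
#' Candidate blobs are split at necks and mutual contacts by a watershed of
#' the (anisotropy-aware) Euclidean distance transform, seeded at its
#' thinned local maxima; each candidate is then fitted with a 3D ellipsoid by
#' second-moment analysis and kept only if it looks glomerular: relative fit
#' residual (1 - Jaccard overlap between candidate and fitted ellipsoid) at
#' most `fit_residual_max`, semi-axis ratio at most `axis_ratio_max`, and
#' volume at least `min_volume`. Survivors are relabelled `1..K`. An empty
#' result is a valid label map with `K = 0`.
#'
#' @param mask Logical foreground array (attribute `voxel_size` in um, as
#'   produced by [binarize_otsu()]), or pass `voxel_size` explicitly.
#' @param fit_residual_max Maximum 1 - Jaccard(candidate, fitted ellipsoid).
#' @param min_volume Minimum instance volume in um^3.
#' @param axis_ratio_max Maximum ratio of largest to smallest fitted
#'   semi-axis; elongated vessel fragments fail this gate.
#' @param min_peak_height Minimum distance-map value (um) for a watershed
#'   seed; half the smallest expected head diameter is a good choice, and the
#'   default (12 um) suppresses seeds inside vascular tubes and necks.
#' @param min_peak_distance Minimum separation (um) between seeds.
#' @param voxel_size Spacing override `(z, y, x)` in um.
#' @return A [label_map()]; attribute `fits` is a tibble with one row per
#'   candidate (kept or rejected) carrying centroid, fitted semi-axes and
#'   residual.
#' @export
separate_instances_ellipse_fit <- function(mask, fit_residual_max = 0.4,
                                           min_volume = 1000,
                                           axis_ratio_max = 3,
                                           min_peak_height = 12,
                                           min_peak_distance = 20,
                                           voxel_size = NULL) {
  vs <- voxel_size %||% attr(mask, "voxel_size")
  if (is.null(vs)) abort("mask carries no voxel_size; pass `voxel_size`.")
  if (!any(mask)) abort("`mask` is empty.")
  d <- dim(mask)
  dist <- cpp_edt3d(mask, d, vs)
  peaks <- cpp_peaks3d(dist, d, vs, pmax(1L, as.integer(round(3 / vs))),
                       min_peak_height, min_peak_distance)
  fits <- empty_fit_table()
  if (length(peaks) == 0) {
    lm <- label_map(array(0L, d), vs)
    attr(lm, "fits") <- fits
    return(lm)
  }
  seeds <- array(0L, d)
  seeds[peaks] <- seq_along(peaks)
  regions <- cpp_watershed3d(dist, seeds, mask, d)
  vox_vol <- prod(vs)
  keep_ids <- integer()
  out <- array(0L, d)
  for (k in seq_along(peaks)) {
    vox <- which(regions == k)
    vol <- length(vox) * vox_vol
    fit <- fit_ellipsoid_moments(vox, d, vs)
    residual <- ellipsoid_fit_residual(vox, fit, d, vs)
    ratio <- max(fit$semi_axes) / max(min(fit$semi_axes), 1e-9)
    kept <- vol >= min_volume && residual <= fit_residual_max &&
            ratio <= axis_ratio_max
    fits <- dplyr::bind_rows(fits, tibble(
      candidate = k, volume_um3 = vol,
      centroid_x = fit$center[1], centroid_y = fit$center[2],
      centroid_z = fit$center[3],
      semi_a = fit$semi_axes[1], semi_b = fit$semi_axes[2],
      semi_c = fit$semi_axes[3],
      fit_residual = residual, axis_ratio = ratio, kept = kept))
    if (kept) {
      keep_ids <- c(keep_ids, k)
      out[vox] <- length(keep_ids)
    }
  }
  fits$label <- ifelse(fits$kept, cumsum(fits$kept), NA_integer_)
  lm <- label_map(out, vs)
  attr(lm, "fits") <- fits
  lm
}

empty_fit_table <- function() {
  tibble(candidate = integer(), volume_um3 = numeric(),
         centroid_x = numeric(), centroid_y = numeric(),
         centroid_z = numeric(), semi_a = numeric(), semi_b = numeric(),
         semi_c = numeric(), fit_residual = numeric(), axis_ratio = numeric(),
         kept = logical())
}

# ellipsoid from the second moments of a voxel set: for a uniform solid
# ellipsoid the covariance eigenvalues are a_i^2 / 5
fit_ellipsoid_moments <- function(vox, dims, vs) {
  zyx <- cbind((vox - 1) %% dims[1] + 1,
               ((vox - 1) %/% dims[1]) %% dims[2] + 1,
               (vox - 1) %/% (dims[1] * dims[2]) + 1)
  w <- voxel_to_world(zyx, vs)
  ctr <- colMeans(w)
  if (nrow(w) < 4) {
    return(list(center = ctr, semi_axes = rep(max(vs) / 2, 3), axes = diag(3)))
  }
  cv <- cov(w) * (nrow(w) - 1) / nrow(w)
  eg <- eigen(cv, symmetric = TRUE)
  semi <- sqrt(5 * pmax(eg$values, 1e-12))
  list(center = ctr, semi_axes = semi, axes = eg$vectors)
}

# 1 - Jaccard between the candidate voxel set and its fitted ellipsoid,
# evaluated on the candidate bounding box dilated by the largest semi-axis
ellipsoid_fit_residual <- function(vox, fit, dims, vs) {
  zyx <- cbind((vox - 1) %% dims[1] + 1,
               ((vox - 1) %/% dims[1]) %% dims[2] + 1,
               (vox - 1) %/% (dims[1] * dims[2]) + 1)
  pad <- ceiling(max(fit$semi_axes) / vs)
  lo <- pmax(apply(zyx, 2, min) - pad[c(1, 2, 3)], 1)
  hi <- pmin(apply(zyx, 2, max) + pad[c(1, 2, 3)], dims)
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  grid <- expand.grid(z = zz, y = yy, x = xx)
  w <- voxel_to_world(as.matrix(grid[, c("z", "y", "x")]), vs)
  q <- sweep(w, 2, fit$center) %*% fit$axes
  inside <- (q[, 1] / fit$semi_axes[1])^2 + (q[, 2] / fit$semi_axes[2])^2 +
            (q[, 3] / fit$semi_axes[3])^2 <= 1
  cand <- array(FALSE, dims)
  cand[vox] <- TRUE
  in_cand <- cand[cbind(grid$z, grid$y, grid$x)]
  inter <- sum(inside & in_cand)
  union <- sum(inside | in_cand)
  if (union == 0) return(1)
  1 - inter / union
}

#' Drop instances near the stack faces
#'
#' Detection near the borders of a light-sheet acquisition is unreliable
#' (truncated or blurred objects), so analysis is confined to the interior:
#' any instance with a voxel centre closer than `margin` to a stack face is
#' removed and the remaining labels are compacted. The default margin, used
#' by [segment_glomeruli()], is 5% of each axis extent.
#'
#' @param labels A [label_map()].
#' @param margin Distance in um, scalar or per-axis `(z, y, x)`; must be
#'   below half the corresponding stack extent.
#' @return A [label_map()] with edge instances removed.
#' @export
exclude_edge_objects <- function(labels, margin) {
  stopifnot(inherits(labels, "label_map"))
  vs <- voxel_size(labels)
  d <- dim(labels)
  extent <- (d - 1) * vs
  margin <- rep(as.numeric(margin), length.out = 3)
  if (any(margin < 0)) abort("`margin` must be nonnegative.")
  if (any(margin > extent / 2))
    abort("`margin` exceeds half the stack extent; nothing could survive.")
  k <- n_labels(labels)
  if (k == 0) return(labels)
  bad <- logical(k)
  for (axis in 1:3) {
    n <- d[axis]
    coord <- (seq_len(n) - 1) * vs[axis]
    near <- which(pmin(coord, extent[axis] - coord) < margin[axis])
    if (!length(near)) next
    sl <- switch(axis, labels[near, , , drop = FALSE],
                 labels[, near, , drop = FALSE],
                 labels[, , near, drop = FALSE])
    hit <- unique(as.integer(sl[sl > 0]))
    bad[hit] <- TRUE
  }
  remap <- integer(k)
  remap[!bad] <- seq_len(sum(!bad))
  out <- array(0L, d)
  pos <- labels > 0
  out[pos] <- remap[labels[pos]]
  lm <- label_map(out, vs)
  attr(lm, "fits") <- attr(labels, "fits")
  lm
}

#' Randomly sample glomerulus instances
#'
#' Draws `min(n, K)` distinct instance ids uniformly without replacement,
#' mirroring the practice of analysing a fixed number of randomly selected
#' glomeruli per kidney (ten in the reference workflow). Deterministic for a
#' given seed; if fewer than `n` instances exist, all are returned with a
#' warning.
#'
#' @param labels A [label_map()] with `K >= 1` instances.
#' @param n Number of instances to draw (default 10).
#' @param seed Integer seed.
#' @return Integer vector of instance ids.
#' @export
sample_glomeruli <- function(labels, n = 10L, seed = 1L) {
  k <- n_labels(labels)
  if (k == 0) abort("label map contains no instances to sample.")
  if (k < n) {
    warn(sprintf("only %d instance(s) available; returning all of them.", k))
    n <- k
  }
  with_seed(seed, sample.int(k, n))
}
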