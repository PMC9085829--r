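#' Volume stacks
#'
#' A `volume_stack` is the container for one channel of a 3D light-sheet
#' acquisition: a numeric array in `(z, y, x)` axis order together with the
#' voxel spacing in micrometres per axis. World coordinates are defined as
#' `(index - 1) * voxel_size` per axis, so voxel `(1, 1, 1)` sits at the
#' origin. The z spacing of a light-sheet stack is typically coarser than the
#' in-plane spacing (4 um plane intervals versus ~1 um pixels); the spacing is
#' carried through every operation and never silently resampled.
#'
#' @param intensities Numeric array, dimensions `(nz, ny, nx)`, nonnegative.
#' @param voxel_size Numeric length-3, micrometres per voxel along `(z, y, x)`.
#' @param provenance Free-text description of where the stack came from.
#'
#' @return A `volume_stack` object (numeric array with `voxel_size` and
#'   `provenance` attributes).
#' @export
#' @examples
#' v <- volume_stack(array(0, c(4, 8, 8)), voxel_size = c(4, 1, 1))
#' dim(v)
#' voxel_size(v)
volume_stack <- function(intensities, voxel_size, provenance = "") {
  if (length(dim(intensities)) != 3L)
    abort("`intensities` must be a 3D array in (z, y, x) order.")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    abort("`voxel_size` must be three positive spacings (z, y, x) in micrometres.")
  if (any(intensities < 0, na.rm = TRUE))
    abort("`intensities` must be nonnegative.")
  structure(intensities,
            voxel_size = setNames(voxel_size, c("z", "y", "x")),
            provenance = provenance,
            class = c("volume_stack", "array"))
}

#' @rdname volume_stack
#' @param x A `volume_stack` or `label_map`.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' @rdname volume_stack
#' @export
voxel_volume <- function(x) prod(attr(x, "voxel_size"))

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf("<volume_stack> %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]  %s\n",
              min(x), max(x), attr(x, "provenance")))
  invisible(x)
}

# world (x,y,z) um coordinates of voxel centres given 1-based (z,y,x) indices
voxel_to_world <- function(zyx_idx, voxel_size) {
  cbind(x = (zyx_idx[, 3] - 1) * voxel_size[3],
        y = (zyx_idx[, 2] - 1) * voxel_size[2],
        z = (zyx_idx[, 1] - 1) * voxel_size[1])
}

#' Read and write volume stacks as multi-page TIFF
#'
#' Stacks are stored as one 16-bit greyscale page per z-plane. Because TIFF
#' spacing tags are dialect-ridden, the voxel spacing travels in a YAML
#' sidecar (`<stem>.yml`) written next to the TIFF; on read the sidecar wins
#' over any `spacing` override only when the override is missing.
#'
#' @param path Path to a `.tif`/`.tiff` file.
#' @param spacing Optional numeric length-3 `(z, y, x)` spacing in um,
#'   overriding the sidecar.
#' @return `read_stack()` returns a [volume_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    abort("multi-channel TIFF pages are not supported; supply one channel.")
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  sidecar <- sidecar_path(path)
  if (is.null(spacing)) {
    if (!file.exists(sidecar))
      abort(c("no voxel spacing available for this stack",
              i = "write a YAML sidecar or pass `spacing = c(z, y, x)`."))
    meta <- yaml::read_yaml(sidecar)
    spacing <- as.numeric(meta$voxel_size_um[c("z", "y", "x")])
  }
  volume_stack(arr, spacing, provenance = path)
}

#' @rdname read_stack
#' @param volume A [volume_stack()].
#' @param bits Bit depth to write (8 or 16).
#' @export
write_stack <- function(volume, path, bits = 16L) {
  stopifnot(inherits(volume, "volume_stack"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  v <- pmin(pmax(unclass(volume), 0), top) / top
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  vs <- voxel_size(volume)
  yaml::write_yaml(list(voxel_size_um = list(z = as.numeric(vs[1]),
                                             y = as.numeric(vs[2]),
                                             x = as.numeric(vs[3])),
                        axis_order = "zyx"),
                   sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yml")

#' Label maps
#'
#' A `label_map` is an integer instance segmentation aligned voxel-for-voxel
#' with the stack it was derived from: 0 is background and `k > 0` the k-th
#' glomerulus instance. Labels are kept consecutive (`1..K`).
#'
#' @param labels Integer array `(nz, ny, nx)`.
#' @param voxel_size Spacing `(z, y, x)` in um, as for [volume_stack()].
#' @return A `label_map` object.
#' @export
label_map <- function(labels, voxel_size) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  u <- sort(unique(as.integer(labels[labels > 0])))
  if (length(u) && !identical(u, seq_along(u)))
    abort("labels must be consecutive integers 1..K.")
  structure(array(as.integer(labels), dim(labels)),
            voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
            class = c("label_map", "array"))
}

#' @rdname label_map
#' @param x A `label_map`.
#' @export
n_labels <- function(x) {
  m <- max(x)
  if (is.na(m) || m < 1) 0L else as.integer(m)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_map> %d x %d x %d voxels (z,y,x), %d instance(s)\n",
              d[1], d[2], d[3], n_labels(x)))
  invisible(x)
}
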