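# internal helpers shared across modules

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seeds, kept below 2^31 - 1
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 49999L * 40009 + index * 7919 + 1) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a zero-length vector.")
  v / n
}

# uniform random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# shift an array along one axis with edge replication
shift_axis <- function(v, axis, by) {
  d <- dim(v)
  idx <- clamp(seq_len(d[axis]) + by, 1L, d[axis])
  switch(axis,
         v[idx, , , drop = FALSE],
         v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

# separable Gaussian blur on a 3D array; sigma given in physical units and
# converted to per-axis voxel sigmas via the voxel spacing
gauss_blur3d <- function(v, sigma_um, voxel_size) {
  d <- dim(v)
  for (axis in 1:3) {
    s <- sigma_um / voxel_size[axis]
    if (s < 0.15) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, d)
    for (k in -r:r) acc <- acc + w[k + r + 1] * shift_axis(v, axis, k)
    v <- acc
  }
  v
}

# central-difference gradient of a 3D array; spacing in um per axis gives
# derivatives in intensity per um
gradient3d <- function(v, voxel_size) {
  list(z = (shift_axis(v, 1, 1) - shift_axis(v, 1, -1)) / (2 * voxel_size[1]),
       y = (shift_axis(v, 2, 1) - shift_axis(v, 2, -1)) / (2 * voxel_size[2]),
       x = (shift_axis(v, 3, 1) - shift_axis(v, 3, -1)) / (2 * voxel_size[3]))
}

# 2D separable Gaussian filter (used by SSIM)
gauss_filter2d <- function(m, sigma, width) {
  r <- (width - 1) %/% 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  shift2 <- function(m, axis, by) {
    d <- dim(m)
    idx <- clamp(seq_len(d[axis]) + by, 1L, d[axis])
    if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  for (axis in 1:2) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (k in -r:r) acc <- acc + w[k + r + 1] * shift2(m, axis, k)
    m <- acc
  }
  m
}
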