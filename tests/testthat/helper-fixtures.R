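# fixtures and independent oracles, built in code at test time

# exact binary rasterization of an ellipsoid by voxel-centre inclusion;
# dims (z, y, x), spacing um, center (x, y, z) um, axes columns = directions
rasterize_ellipsoid <- function(dims, vs, center, semi, axes = diag(3)) {
  zyx <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                               x = seq_len(dims[3])))
  w <- cbind((zyx[, 3] - 1) * vs[3], (zyx[, 2] - 1) * vs[2],
             (zyx[, 1] - 1) * vs[1])
  q <- sweep(w, 2, center) %*% axes
  inside <- (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
            (q[, 3] / semi[3])^2 <= 1
  arr <- array(FALSE, dims)
  arr[zyx[inside, , drop = FALSE]] <- TRUE
  arr
}

# binary sphere-with-cylindrical-neck label map (1 um voxels by default)
rasterize_sphere_on_neck <- function(r_head = 25, r_neck = 7, neck_len = 25,
                                     vs = c(1, 1, 1), pad = 4) {
  total <- neck_len + 2 * r_head + 2 * pad
  side <- 2 * r_head + 2 * pad
  dims <- c(ceiling(total / vs[1]) + 1, ceiling(side / vs[2]) + 1,
            ceiling(side / vs[3]) + 1)
  cx <- (dims[3] - 1) * vs[3] / 2
  cy <- (dims[2] - 1) * vs[2] / 2
  zc <- pad + neck_len + r_head  # head centre height (z axis = neck axis)
  zyx <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                               x = seq_len(dims[3])))
  w <- cbind(x = (zyx[, 3] - 1) * vs[3], y = (zyx[, 2] - 1) * vs[2],
             z = (zyx[, 1] - 1) * vs[1])
  in_head <- (w[, "x"] - cx)^2 + (w[, "y"] - cy)^2 + (w[, "z"] - zc)^2 <= r_head^2
  in_neck <- (w[, "x"] - cx)^2 + (w[, "y"] - cy)^2 <= r_neck^2 &
             w[, "z"] >= pad & w[, "z"] <= zc
  arr <- array(0L, dims)
  arr[zyx[in_head | in_neck, , drop = FALSE]] <- 1L
  label_map(arr, vs)
}

# brute-force voxelization of a closed mesh by z-column ray parity
voxelize_mesh_count <- function(mesh, h = 0.5) {
  v <- mesh$vertices
  tr <- mesh$triangles
  lo <- apply(v, 2, min) - h
  hi <- apply(v, 2, max) + h
  # offset the sample grid so rays never align with faces or vertices
  off <- h * 0.5070913
  xs <- seq(lo[1] + off, hi[1], by = h)
  ys <- seq(lo[2] + off, hi[2], by = h)
  zs <- seq(lo[3] + off, hi[3], by = h)
  inside_total <- 0
  for (xi in xs) {
    for (yi in ys) {
      # ray along +z from below: collect crossing heights
      crossings <- numeric()
      for (t in seq_len(nrow(tr))) {
        p1 <- v[tr[t, 1], ]; p2 <- v[tr[t, 2], ]; p3 <- v[tr[t, 3], ]
        # 2D point-in-triangle in the xy plane
        d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
        if (abs(d) < 1e-12) next
        l1 <- ((p2[2] - p3[2]) * (xi - p3[1]) + (p3[1] - p2[1]) * (yi - p3[2])) / d
        l2 <- ((p3[2] - p1[2]) * (xi - p3[1]) + (p1[1] - p3[1]) * (yi - p3[2])) / d
        l3 <- 1 - l1 - l2
        if (l1 < 0 || l2 < 0 || l3 < 0) next
        crossings <- c(crossings, l1 * p1[3] + l2 * p2[3] + l3 * p3[3])
      }
      if (!length(crossings)) next
      crossings <- sort(crossings)
      inside_total <- inside_total +
        sum(vapply(zs, function(z) sum(crossings < z) %% 2 == 1, logical(1)))
    }
  }
  inside_total * h^3
}

# exhaustive between-class-variance maximizer over the same histogram bins
brute_force_otsu <- function(x, n_bins = 256L) {
  rng <- range(x)
  bin <- pmin(as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  best_k <- NA_integer_
  best_v <- -Inf
  for (k in seq_len(n_bins - 1)) {
    g0 <- bin <= k
    w0 <- mean(g0)
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(bin[g0]) - mean(bin[!g0]))^2
    if (v > best_v) {
      best_v <- v
      best_k <- k
    }
  }
  rng[1] + best_k / n_bins * diff(rng)
}

# closed-form caliper width of an ellipsoid along direction u:
# w(u) = 2 sqrt(u' R diag(a^2) R' u)
ellipsoid_width <- function(u, semi, axes = diag(3)) {
  m <- axes %*% diag(semi^2) %*% t(axes)
  2 * sqrt(as.numeric(t(u) %*% m %*% u))
}

# surface of revolution around the z axis: radius_fn(z) >= 0, closed at the
# top by an apex (radius must taper to ~0), optionally open at the base
revolve_mesh <- function(radius_fn, zs, segments = 48, open_base = TRUE) {
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  verts <- NULL
  rows <- list()
  for (z in zs[-length(zs)]) {
    r <- radius_fn(z)
    base <- if (is.null(verts)) 0 else nrow(verts)
    verts <- rbind(verts, cbind(r * cos(th), r * sin(th), z))
    rows[[length(rows) + 1]] <- base + seq_len(segments)
  }
  verts <- rbind(verts, c(0, 0, zs[length(zs)]))
  apex <- nrow(verts)
  tr <- NULL
  nxt <- c(2:segments, 1)
  for (i in seq_len(length(rows) - 1)) {
    a <- rows[[i]]; b <- rows[[i + 1]]
    tr <- rbind(tr, cbind(a, a[nxt], b[nxt]), cbind(a, b[nxt], b))
  }
  top <- rows[[length(rows)]]
  tr <- rbind(tr, cbind(top, top[nxt], apex))
  if (!open_base) {
    verts <- rbind(verts, c(0, 0, zs[1]))
    bc <- nrow(verts)
    bot <- rows[[1]]
    tr <- rbind(tr, cbind(bot[nxt], bot, bc))
  }
  surface_mesh(verts, tr)
}

# random rotation matrix under the current RNG
test_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol)
}
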