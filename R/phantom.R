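#' Generate a synthetic kidney stack with known ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: glomerular heads are
#' random ellipsoids placed without mutual overlap and away from the stack
#' faces, each joined by a cylindrical neck (rendered at head intensity, as
#' both are membrane-labelled) to a random branching tree of dimmer vascular
#' capsules. Structures are rasterized with a one-voxel soft edge on a fine
#' isotropic grid at the in-plane spacing, convolved with the Gaussian PSF,
#' resampled to the requested anisotropic spacing, and finally corrupted by
#' the configured noise. The returned ground-truth table lists, per
#' glomerulus, the placed geometry and its analytic volume and diameters in
#' the same world coordinates (um) as the stack. Identical specs (including
#' the seed) render bit-identical phantoms.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [volume_stack()]) and `truth` (a tibble:
#'   `id`, `center_x/y/z`, semi-axes `a/b/c_um` sorted descending, major-axis
#'   direction `dir_a_x/y/z`, `neck_radius_um`, `neck_length_um`, neck
#'   direction `neck_dir_x/y/z`, `head_volume_um3`, `dmax_um`, `dmin_um`,
#'   `neck_diameter_um`).
#' @export
generate_kidney_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    # world points are (x, y, z) um; arrays are (z, y, x)
    extent <- ((spec$grid_shape - 1) * spec$voxel_size)[3:1]
    s0 <- min(spec$voxel_size)
    fine_dim <- as.integer(round(extent[3:1] / s0)) + 1L
    gloms <- place_glomeruli(spec, extent)
    vessels <- grow_vessel_tree(spec, extent, gloms)
    img <- array(spec$background_intensity, fine_dim)
    for (vseg in vessels)
      img <- paint_capsule(img, s0, vseg$p0, vseg$p1, vseg$radius,
                           spec$vessel_intensity, spec$background_intensity)
    for (g in gloms) {
      img <- paint_capsule(img, s0, g$neck_p0, g$neck_p1, g$neck_radius,
                           spec$head_intensity, spec$background_intensity)
      img <- paint_ellipsoid(img, s0, g$center, g$semi_axes, g$axes,
                             spec$head_intensity, spec$background_intensity)
    }
    if (spec$psf_sigma > 0)
      img <- gauss_blur3d(img, spec$psf_sigma, rep(s0, 3))
    for (axis in 1:3)
      if (spec$voxel_size[axis] > s0 * (1 + 1e-9))
        img <- resample_axis_linear(img, axis, s0, spec$voxel_size[axis])
    if (spec$poisson_noise)
      img <- array(rpois(length(img), pmax(img, 0)), dim(img))
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    img <- pmax(img, 0)
    vol <- volume_stack(array(img, spec$grid_shape), spec$voxel_size,
                        provenance = sprintf("kidney phantom seed %d", spec$seed))
    list(volume = vol, truth = ground_truth_table(gloms))
  })
}

# geometry-only phantom: same RNG stream prefix as the full render, so the
# truth table matches what generate_kidney_phantom() would produce
generate_phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    extent <- ((spec$grid_shape - 1) * spec$voxel_size)[3:1]
    list(volume = NULL, truth = ground_truth_table(place_glomeruli(spec, extent)))
  })
}

ground_truth_table <- function(gloms) {
  if (!length(gloms)) {
    return(tibble(id = integer(), center_x = numeric(), center_y = numeric(),
                  center_z = numeric(), a_um = numeric(), b_um = numeric(),
                  c_um = numeric(), dir_a_x = numeric(), dir_a_y = numeric(),
                  dir_a_z = numeric(), neck_radius_um = numeric(),
                  neck_length_um = numeric(), neck_dir_x = numeric(),
                  neck_dir_y = numeric(), neck_dir_z = numeric(),
                  head_volume_um3 = numeric(), dmax_um = numeric(),
                  dmin_um = numeric(), neck_diameter_um = numeric()))
  }
  purrr::map_dfr(seq_along(gloms), function(i) {
    g <- gloms[[i]]
    ord <- order(-g$semi_axes)
    a <- g$semi_axes[ord]
    tibble(id = i, center_x = g$center[1], center_y = g$center[2],
           center_z = g$center[3], a_um = a[1], b_um = a[2], c_um = a[3],
           dir_a_x = g$axes[1, ord[1]], dir_a_y = g$axes[2, ord[1]],
           dir_a_z = g$axes[3, ord[1]],
           neck_radius_um = g$neck_radius, neck_length_um = g$neck_length,
           neck_dir_x = g$neck_dir[1], neck_dir_y = g$neck_dir[2],
           neck_dir_z = g$neck_dir[3],
           head_volume_um3 = 4 / 3 * pi * prod(a),
           dmax_um = 2 * a[1], dmin_um = 2 * a[3],
           neck_diameter_um = 2 * g$neck_radius)
  })
}

# non-overlapping head placement on a jittered lattice: cells are spaced so
# that any two heads fit side by side, n random cells are occupied, and each
# centre is jittered within the slack left in its cell
place_glomeruli <- function(spec, extent) {
  gloms <- list()
  if (spec$n_glomeruli == 0) return(gloms)
  hs <- spec$head_semi_axes_dist
  semi_all <- lapply(seq_len(spec$n_glomeruli), function(i)
    truncated_normal(3, hs["mean"], hs["sd"], lo = 0.4 * hs["mean"]))
  rmax_all <- vapply(semi_all, max, numeric(1))
  gap <- 2
  pitch <- 2 * max(rmax_all) + gap
  lo <- rep(spec$edge_margin + max(rmax_all), 3)
  hi <- extent - spec$edge_margin - max(rmax_all)
  if (any(hi < lo))
    abort("placement failure: head plus edge margin exceeds the stack extent.")
  axes_pos <- lapply(1:3, function(a) {
    k <- max(1L, floor((hi[a] - lo[a]) / pitch) + 1L)
    lo[a] + (seq_len(k) - 1) * pitch + (hi[a] - lo[a] - (k - 1) * pitch) / 2
  })
  cells <- as.matrix(expand.grid(axes_pos[[1]], axes_pos[[2]], axes_pos[[3]]))
  if (nrow(cells) < spec$n_glomeruli)
    abort(sprintf(paste0("placement failure: only %d non-overlapping head ",
                         "sites fit this grid (requested %d); reduce ",
                         "n_glomeruli or enlarge grid_shape."),
                  nrow(cells), spec$n_glomeruli))
  pick <- sample.int(nrow(cells), spec$n_glomeruli)
  # place all heads first, then attach necks kept clear of every head so
  # instances can never fuse through a foreign neck
  for (i in seq_len(spec$n_glomeruli)) {
    semi <- semi_all[[i]]
    axes <- random_rotation()
    slack <- (pitch - 2 * max(semi) - gap) / 2 + (max(rmax_all) - max(semi))
    jit <- runif(3, -1, 1) * clamp(slack, 0, 5)
    center <- clamp(cells[pick[i], ] + jit, lo, hi)
    gloms[[i]] <- list(center = center, semi_axes = semi, axes = axes)
  }
  for (i in seq_len(spec$n_glomeruli)) {
    neck <- sample_neck(spec, gloms[[i]]$center, gloms[[i]]$semi_axes,
                        gloms[[i]]$axes, extent, others = gloms[-i])
    if (is.null(neck))
      abort(sprintf(paste0("placement failure: no valid neck direction for ",
                           "glomerulus %d; enlarge grid_shape or shorten ",
                           "neck_length_dist."), i))
    gloms[[i]] <- c(gloms[[i]], neck)
  }
  gloms
}

# closest approach of two 3D segments (a0-a1, b0-b1)
segment_distance <- function(a0, a1, b0, b1) {
  u <- a1 - a0
  v <- b1 - b0
  w <- a0 - b0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b^2
  s <- if (den > 1e-12) clamp((b * e - cc * d) / den, 0, 1) else 0
  t <- if (cc > 1e-12) clamp((b * s + e) / cc, 0, 1) else 0
  s <- if (a > 1e-12) clamp((b * t - d) / a, 0, 1) else 0
  p <- a0 + s * u
  q <- b0 + t * v
  sqrt(sum((p - q)^2))
}

# Gaussian draws truncated to [lo, mean + 2 sd]; the upper cap bounds the
# largest possible head so lattice placement capacity can be guaranteed
truncated_normal <- function(n, mean, sd, lo, hi = mean + 2 * sd) {
  x <- rnorm(n, mean, sd)
  bad <- x <= lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= lo | x > hi
  }
  x
}

# a neck runs outward from the head surface along a random direction whose
# far end stays inside the stack and, preferably, clear of other heads
sample_neck <- function(spec, center, semi, axes, extent, others = list(),
                        max_dir_tries = 60L) {
  nr <- truncated_normal(1, spec$neck_radius_dist["mean"],
                         spec$neck_radius_dist["sd"],
                         lo = 0.3 * spec$neck_radius_dist["mean"])
  nl <- truncated_normal(1, spec$neck_length_dist["mean"],
                         spec$neck_length_dist["sd"],
                         lo = 0.3 * spec$neck_length_dist["mean"])
  for (try in seq_len(max_dir_tries)) {
    d <- normalize3(rnorm(3))
    q <- as.numeric(t(axes) %*% d)
    t_surf <- 1 / sqrt(sum((q / semi)^2))
    p1 <- center + (t_surf + nl) * d
    clear <- all(vapply(others, function(g) {
      # keep the neck axis away from other heads and other necks, so
      # instances can never fuse and ground truth stays unambiguous
      t <- clamp(sum((g$center - center) * d), 0, t_surf + nl)
      p <- center + t * d
      if (sqrt(sum((p - g$center)^2)) <= max(g$semi_axes) + nr + 1) return(FALSE)
      if (!is.null(g$neck_p0)) {
        if (segment_distance(center, p1, g$neck_p0, g$neck_p1) <=
            nr + g$neck_radius + 1) return(FALSE)
      }
      TRUE
    }, logical(1)))
    if (!clear) next
    if (all(p1 > nr + 2) && all(p1 < extent - nr - 2)) {
      # start slightly inside the head so the attachment is seamless
      p0 <- center + 0.9 * t_surf * d
      return(list(neck_p0 = p0, neck_p1 = p1, neck_radius = nr,
                  neck_length = nl, neck_dir = d))
    }
  }
  NULL
}

# random branching capsule tree reaching the target volume fraction; necks
# are extended into the tree so every glomerulus hangs off the vasculature
grow_vessel_tree <- function(spec, extent, gloms, radius = 3,
                             max_segments = 4000L) {
  segs <- list()
  total_vol <- prod(extent)
  target <- spec$vessel_density * total_vol
  for (g in gloms) {
    p2 <- clamp(g$neck_p1 + g$neck_dir * 25, 2, extent - 2)
    segs[[length(segs) + 1]] <- list(p0 = g$neck_p1, p1 = p2, radius = radius)
  }
  if (target <= 0) return(segs)
  nodes <- list(runif(3) * (extent - 4) + 2)
  acc <- 0
  while (acc < target && length(segs) < max_segments) {
    from <- nodes[[sample.int(length(nodes), 1)]]
    d <- normalize3(rnorm(3))
    len <- runif(1, 20, 60)
    to <- clamp(from + d * len, 2, extent - 2)
    if (sqrt(sum((to - from)^2)) < 5) next
    segs[[length(segs) + 1]] <- list(p0 = from, p1 = to, radius = radius)
    nodes[[length(nodes) + 1]] <- to
    acc <- acc + pi * radius^2 * sqrt(sum((to - from)^2))
  }
  segs
}

# --- rasterization helpers (fine isotropic grid, spacing s0) ---------------

# voxel-index bounding box (1-based) for a world-space box; lo_w/hi_w are
# (x, y, z) world points, dims is the (z, y, x) array shape
bbox_indices <- function(lo_w, hi_w, s0, dims) {
  lo <- pmax(floor(lo_w[3:1] / s0) + 1, 1)
  hi <- pmin(ceiling(hi_w[3:1] / s0) + 1, dims)
  if (any(hi < lo)) return(NULL)
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

# world coordinates of a (z, y, x) index grid; returns n x 3 matrix (x, y, z)
grid_world <- function(bb, s0) {
  nz <- length(bb$z); ny <- length(bb$y); nx <- length(bb$x)
  cbind(x = rep((bb$x - 1) * s0, each = nz * ny),
        y = rep(rep((bb$y - 1) * s0, each = nz), times = nx),
        z = rep((bb$z - 1) * s0, times = ny * nx))
}

paint_soft <- function(img, bb, sd, s0, intensity, background) {
  cov <- clamp(0.5 - sd / s0, 0, 1)
  if (!any(cov > 0)) return(img)
  val <- background + (intensity - background) * cov
  cur <- img[bb$z, bb$y, bb$x]
  img[bb$z, bb$y, bb$x] <- pmax(cur, array(val, dim(cur)))
  img
}

paint_ellipsoid <- function(img, s0, center, semi, axes, intensity, background) {
  dims <- dim(img)
  r <- max(semi) + 2 * s0
  bb <- bbox_indices(center - r, center + r, s0, dims)
  if (is.null(bb)) return(img)
  w <- grid_world(bb, s0)
  q <- sweep(w, 2, center) %*% axes
  f <- sqrt((q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 + (q[, 3] / semi[3])^2)
  gn <- sqrt(q[, 1]^2 / semi[1]^4 + q[, 2]^2 / semi[2]^4 + q[, 3]^2 / semi[3]^4)
  sd <- ifelse(gn > 1e-12, f * (f - 1) / gn, -max(semi))
  paint_soft(img, bb, sd, s0, intensity, background)
}

paint_capsule <- function(img, s0, p0, p1, radius, intensity, background) {
  dims <- dim(img)
  lo <- pmin(p0, p1) - radius - 2 * s0
  hi <- pmax(p0, p1) + radius + 2 * s0
  bb <- bbox_indices(lo, hi, s0, dims)
  if (is.null(bb)) return(img)
  w <- grid_world(bb, s0)
  axis <- p1 - p0
  len2 <- sum(axis^2)
  t <- ((w[, 1] - p0[1]) * axis[1] + (w[, 2] - p0[2]) * axis[2] +
        (w[, 3] - p0[3]) * axis[3]) / len2
  t <- clamp(t, 0, 1)
  dx <- w[, 1] - (p0[1] + t * axis[1])
  dy <- w[, 2] - (p0[2] + t * axis[2])
  dz <- w[, 3] - (p0[3] + t * axis[3])
  sd <- sqrt(dx^2 + dy^2 + dz^2) - radius
  paint_soft(img, bb, sd, s0, intensity, background)
}

#' Generate a paired normal / diseased phantom cohort
#'
#' Draws `n_per_group` phantoms per arm: the first arm from `normal_spec`,
#' the second from the same spec with head semi-axes scaled by
#' `effect["head"]` and neck radii by `effect["neck"]`, emulating the
#' glomerular enlargement of nephrotoxic nephritis. Per-volume seeds are
#' derived deterministically from `normal_spec$seed`, so the cohort is fully
#' reproducible.
#'
#' @param normal_spec A [phantom_spec()] for the healthy arm.
#' @param effect Named scale factors `c(head = , neck = )`, each >= 1.
#' @param n_per_group Volumes per arm; scalar, or length 2 for unequal arms
#'   `(normal, diseased)`.
#' @param render Rasterize the stacks (default). With `render = FALSE` only
#'   the ground-truth tables are produced (`volume` is `NULL`); the tables
#'   are identical to the rendered case because geometry is drawn before any
#'   rendering noise.
#' @return A list with elements `normal` and `ntn`, each a list of phantom
#'   results as returned by [generate_kidney_phantom()]; attribute `effect`
#'   records the factors.
#' @export
generate_condition_cohort <- function(normal_spec,
                                      effect = c(head = 1.3, neck = 1.3),
                                      n_per_group = 3L, render = TRUE) {
  stopifnot(inherits(normal_spec, "phantom_spec"))
  effect <- effect[c("head", "neck")]
  if (any(is.na(effect)) || any(effect < 1))
    abort("`effect` must supply head and neck factors >= 1.")
  n_per_group <- rep(as.integer(n_per_group), length.out = 2)
  if (any(n_per_group < 1)) abort("`n_per_group` must be >= 1.")
  master <- normal_spec$seed
  arm <- function(base_spec, n, offset) {
    lapply(seq_len(n), function(i) {
      s <- base_spec
      s$seed <- derive_seed(master, offset + i)
      s <- structure(s, class = "phantom_spec")
      if (render) generate_kidney_phantom(s) else generate_phantom_truth(s)
    })
  }
  ntn_spec <- scale_phantom_spec(normal_spec, effect["head"], effect["neck"])
  structure(list(normal = arm(normal_spec, n_per_group[1], 0L),
                 ntn = arm(ntn_spec, n_per_group[2], 1000L)),
            effect = effect, class = "condition_cohort")
}
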