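# anchor points, orientation, stepped profiles and the head/neck features

test_that("an open-based capsule anchors base at the disc and tip at the apex", {
  m <- mesh_capsule(radius = 8, length = 40, open_base = TRUE)
  a <- extract_anchor_points(m)
  expect_lt(sqrt(sum((a$central_base_point - c(0, 0, 0))^2)), 1e-6)
  expect_lt(sqrt(sum((a$tip - c(0, 0, 48))^2)), 1e-6)
})

test_that("a south-pole reference on a sphere puts the tip at the north pole", {
  m <- mesh_icosphere(10, 3)
  a <- extract_anchor_points(m, base_reference = c(0, 0, -10))
  expect_lt(sqrt(sum((a$tip - c(0, 0, 10))^2)), 1)  # within mesh resolution
})

test_that("the centroid of a closed sphere mesh is its geometric centre", {
  m <- mesh_icosphere(10, 3, center = c(5, -3, 2))
  a <- extract_anchor_points(m, base_reference = "auto")
  expect_lt(sqrt(sum((a$centroid - c(5, -3, 2))^2)), 1e-2)
})

test_that("a closed mesh without a base reference is refused", {
  expect_error(extract_anchor_points(mesh_icosphere(5, 2)), "base reference")
})

test_that("orientation is the normalized base-to-centroid direction", {
  a <- structure(list(central_base_point = c(x = 0, y = 0, z = 0),
                      centroid = c(x = 0, y = 0, z = 5)),
                 class = "anchor_points")
  expect_equal(compute_orientation(a), c(x = 0, y = 0, z = 1))
  b <- structure(list(central_base_point = a$centroid, centroid = a$central_base_point),
                 class = "anchor_points")
  expect_equal(compute_orientation(b), -compute_orientation(a))
  set.seed(8)
  for (i in 1:5) {
    p <- rnorm(3); q <- rnorm(3)
    o <- compute_orientation(structure(list(central_base_point = p, centroid = q),
                                       class = "anchor_points"))
    expect_lt(abs(sqrt(sum(o^2)) - 1), 1e-9)
  }
  same <- structure(list(central_base_point = c(1, 2, 3), centroid = c(1, 2, 3)),
                    class = "anchor_points")
  expect_error(compute_orientation(same), "coincide")
})

capsule_profile <- function(step_height = 2) {
  m <- mesh_capsule(radius = 10, length = 80, segments = 64, rings = 40,
                    open_base = TRUE)
  a <- extract_anchor_points(m)
  o <- compute_orientation(a)
  list(mesh = m, anchors = a, orientation = o,
       profile = stepped_profile(m, o, a, step_height))
}

test_that("interior steps of a cylinder have circular cross-sections of 20 um", {
  cp <- capsule_profile()
  interior <- cp$profile[cp$profile$n_vertices > 0 &
                         cp$profile$s_mid > 5 & cp$profile$s_mid < 70, ]
  expect_true(all(abs(interior$d_max - 20) < 0.5))
  expect_true(all(abs(interior$d_min - 20) < 0.5))
})

test_that("step Feret widths match the analytic ellipsoid caliper oracle", {
  # prolate ellipsoid along z: semi-axes (axial 40, transverse 25 and 15)
  set.seed(21)
  m <- mesh_icosphere(1, 4)
  v <- m$vertices %*% diag(c(25, 15, 40))
  em <- surface_mesh(v, m$triangles)
  a <- extract_anchor_points(em, base_reference = c(0, 0, -40))
  o <- c(0, 0, 1)
  prof <- stepped_profile(em, o, a, step_height = 2)
  hd <- head_diameters(prof)
  expect_lt(abs(hd["hmax"] - 50) / 50, 0.02)
  expect_lt(abs(hd["hmin"] - 30) / 30, 0.04)
  # per-step check against the closed-form section widths of the ellipsoid:
  # a step spanning [z0, z1] is widest at the height nearest the equator, so
  # its Feret width is 2 a sqrt(1 - (z_near/c)^2)
  sub <- prof[prof$n_vertices > 20 & abs(prof$center_z) < 30, ]
  z_near <- pmax(abs(sub$center_z) - 1, 0)  # half the 2 um step height
  expected <- 2 * 25 * sqrt(1 - (z_near / 40)^2)
  expect_lt(max(abs(sub$d_max - expected) / expected), 0.06)
})

test_that("a step height spanning the whole mesh yields one step", {
  m <- mesh_capsule(radius = 5, length = 20, open_base = TRUE)
  a <- extract_anchor_points(m)
  o <- compute_orientation(a)
  expect_warning(prof <- stepped_profile(m, o, a, step_height = 100))
  expect_equal(sum(prof$n_vertices > 0), 1L)
})

test_that("L of a straight capsule approaches its height", {
  cp <- capsule_profile(step_height = 2)
  L <- curve_length_L(cp$profile)
  expect_lt(abs(L - 90), 2 + 2)  # height 90 um, tolerance ~ step height
})

test_that("L along a circular arc matches the analytic arc length", {
  # step centres placed on a quarter circle of radius 50
  th <- seq(0, pi / 2, length.out = 200)
  prof <- tibble::tibble(step = seq_along(th), s_mid = seq_along(th),
                         center_x = 50 * cos(th), center_y = 50 * sin(th),
                         center_z = 0, d_max = 1, d_min = 1,
                         n_vertices = 10L)
  expect_rel_equal(curve_length_L(prof), 50 * pi / 2, 0.01)
})

test_that("bending a capsule increases L beyond the straight chord", {
  m <- mesh_capsule(radius = 8, length = 80, segments = 48, rings = 60,
                    open_base = TRUE)
  v <- m$vertices
  # banana bend: shear x by a quadratic in z
  v[, 1] <- v[, 1] + 0.008 * v[, 3]^2
  bent <- surface_mesh(v, m$triangles)
  a <- extract_anchor_points(bent)
  o <- compute_orientation(a)
  prof <- stepped_profile(bent, o, a, step_height = 2)
  ctr <- prof[prof$n_vertices > 0, c("center_x", "center_y", "center_z")]
  chord <- sqrt(sum((ctr[nrow(ctr), ] - ctr[1, ])^2))
  expect_gt(curve_length_L(prof), chord + 1)
})

test_that("fewer than two non-empty steps cannot define L", {
  prof <- tibble::tibble(step = 1L, s_mid = 1, center_x = 0, center_y = 0,
                         center_z = 0, d_max = 1, d_min = 1, n_vertices = 5L)
  expect_error(curve_length_L(prof), "two non-empty steps")
})

sphere_on_neck_features <- function(r_head = 25, r_neck = 7, neck_len = 25,
                                    step_height = 2, ...) {
  lab <- rasterize_sphere_on_neck(r_head, r_neck, neck_len)
  mesh <- mesh_from_label(lab, 1L)
  mesh <- smooth_curvature_flow(mesh, 10, 0.1)
  glomerulus_features(mesh, base_reference = "auto",
                      step_height = step_height, ...)
}

test_that("a sphere head on a thin neck recovers hMax, hMin and nMax", {
  f <- sphere_on_neck_features(r_head = 25, r_neck = 7, neck_len = 25)
  expect_rel_equal(f$hmax_um, 50, 0.05)
  expect_rel_equal(f$hmin_um, 50, 0.05)
  expect_rel_equal(f$nmax_um, 14, 0.1)
  expect_gte(f$hmax_um, f$hmin_um)
  expect_lt(f$nmax_um, f$hmax_um)
  expect_rel_equal(f$volume_um3, 4 / 3 * pi * 25^3 + pi * 49 * 25, 0.06)
})

test_that("a conical neck widening toward the base reads its base diameter", {
  # neck radius 5 -> 10 toward the base, then a 20 um head, apex-closed
  rad <- function(z) {
    if (z <= 30) 10 - 5 * z / 30
    else sqrt(pmax(20^2 - (z - 50)^2, 0))
  }
  zs <- c(seq(0, 30, by = 1.5), seq(31, 69.5, by = 1.5), 70)
  m <- revolve_mesh(rad, zs, segments = 64, open_base = TRUE)
  a <- extract_anchor_points(m)
  o <- compute_orientation(a)
  prof <- stepped_profile(m, o, a, step_height = 2)
  nmax <- neck_diameter_nMax(prof)
  expect_rel_equal(nmax, 20, 0.08)
})

test_that("feature extraction is deterministic and rigid-motion invariant", {
  f1 <- sphere_on_neck_features()
  f2 <- sphere_on_neck_features()
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  lab <- rasterize_sphere_on_neck()
  mesh <- smooth_curvature_flow(mesh_from_label(lab, 1L), 10, 0.1)
  f0 <- glomerulus_features(mesh, base_reference = "auto", step_height = 2)
  set.seed(14)
  for (i in 1:2) {
    rot <- test_rotation()
    tmesh <- glomorph:::transform_mesh(mesh, rot, rnorm(3, 0, 50))
    ft <- glomerulus_features(tmesh, base_reference = "auto", step_height = 2)
    for (col in c("volume_um3", "hmax_um", "hmin_um", "nmax_um", "L_um"))
      expect_lt(abs(ft[[col]] / f0[[col]] - 1), 0.01)
  }
})

test_that("scaling the head scales recovered hMax proportionally", {
  base <- sphere_on_neck_features(r_head = 20)
  for (s in c(1.2, 1.5)) {
    scaled <- sphere_on_neck_features(r_head = 20 * s)
    expect_lt(abs(scaled$hmax_um / base$hmax_um / s - 1), 0.05)
  }
})

test_that("all features are strictly positive with unit orientation", {
  f <- sphere_on_neck_features()
  expect_true(all(unlist(f[c("volume_um3", "hmax_um", "hmin_um",
                             "nmax_um", "L_um")]) > 0))
  expect_lt(abs(sqrt(f$orient_x^2 + f$orient_y^2 + f$orient_z^2) - 1), 1e-9)
})

test_that("stage errors name the failing stage", {
  expect_error(glomerulus_features(mesh_icosphere(5, 2), base_reference = NULL),
               "anchor_points")
})
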