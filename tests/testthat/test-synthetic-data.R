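# phantom generator: ground-truth fidelity, determinism, cohort scaling

small_spec <- function(...) {
  phantom_spec(grid_shape = c(30L, 100L, 100L), voxel_size = c(4, 1, 1),
               n_glomeruli = 1L, head_semi_axes_dist = c(25, 1),
               neck_radius_dist = c(6, 0.5), neck_length_dist = c(20, 2),
               edge_margin = 6, seed = 5L, ...)
}

test_that("empty phantom carries vessels only and an empty truth table", {
  spec <- phantom_spec(grid_shape = c(12L, 40L, 40L), n_glomeruli = 0L,
                       noise_sd = 0, seed = 2L)
  ph <- generate_kidney_phantom(spec)
  expect_equal(nrow(ph$truth), 0)
  expect_lte(max(ph$volume), spec$vessel_intensity)
  expect_gte(min(ph$volume), spec$background_intensity - 1e-9)
})

test_that("a spherical head's analytic truth volume is (4/3) pi r^3", {
  spec <- small_spec()
  spec$head_semi_axes_dist <- c(mean = 30, sd = 1e-9)
  spec <- structure(spec, class = "phantom_spec")
  ph <- generate_kidney_phantom(spec)
  expect_equal(ph$truth$head_volume_um3, 4 / 3 * pi * 30^3, tolerance = 1e-6)
  expect_equal(ph$truth$dmax_um, 60, tolerance = 1e-6)
})

test_that("equal specs and seeds render bit-identical phantoms", {
  a <- generate_kidney_phantom(small_spec())
  b <- generate_kidney_phantom(small_spec())
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(a$truth, b$truth)
})

test_that("noise- and PSF-free ellipsoid rendering matches analytic volume within 2%", {
  set.seed(42)
  for (semi in list(c(25, 20, 15), c(12, 10, 8))) {
    axes <- test_rotation()
    img <- array(0, c(70, 70, 70))
    img <- glomorph:::paint_ellipsoid(img, 1, center = c(34, 34, 34),
                                      semi = semi, axes = axes,
                                      intensity = 1, background = 0)
    vol <- sum(img >= 0.5)  # half-coverage boundary = the analytic surface
    expect_rel_equal(vol, 4 / 3 * pi * prod(semi), 0.02)
  }
})

test_that("stack spacing honours the phantom spec and is never silently resampled", {
  ph <- generate_kidney_phantom(small_spec())
  expect_equal(unname(voxel_size(ph$volume)), c(4, 1, 1))
  expect_equal(dim(ph$volume), c(30L, 100L, 100L))
})

test_that("overcrowded specs fail with an explicit placement error", {
  expect_error(phantom_spec(grid_shape = c(12L, 60L, 60L), n_glomeruli = 8L),
               "grid too small")
})

test_that("null effect leaves the two arms' truth distributions matched", {
  spec <- phantom_spec(grid_shape = c(40L, 120L, 120L), voxel_size = c(4, 2, 2),
                       n_glomeruli = 4L, seed = 9L)
  co <- generate_condition_cohort(spec, effect = c(head = 1, neck = 1),
                                  n_per_group = 25L, render = FALSE)
  a <- unlist(lapply(co$normal, function(p) p$truth$a_um))
  b <- unlist(lapply(co$ntn, function(p) p$truth$a_um))
  expect_lt(abs(mean(a) / mean(b) - 1), 0.03)
})

test_that("a 1.3x head effect scales true volumes by 2.197 in expectation", {
  spec <- phantom_spec(grid_shape = c(40L, 120L, 120L), voxel_size = c(4, 2, 2),
                       n_glomeruli = 4L, seed = 9L)
  co <- generate_condition_cohort(spec, effect = c(head = 1.3, neck = 1.3),
                                  n_per_group = 80L, render = FALSE)
  va <- unlist(lapply(co$normal, function(p) p$truth$head_volume_um3))
  vb <- unlist(lapply(co$ntn, function(p) p$truth$head_volume_um3))
  expect_lt(abs(mean(vb) / mean(va) / 1.3^3 - 1), 0.05)
  expect_length(co$normal, 80L)
  expect_length(co$ntn, 80L)
})

test_that("cohort arm counts honour n_per_group", {
  spec <- phantom_spec(grid_shape = c(30L, 100L, 100L), n_glomeruli = 1L,
                       seed = 4L)
  co <- generate_condition_cohort(spec, c(head = 1, neck = 1),
                                  n_per_group = 3L, render = FALSE)
  expect_length(co$normal, 3L)
  expect_length(co$ntn, 3L)
})

test_that("outline pairs follow the square law of linear scaling", {
  for (sc in c(1, 1.1, 0.5)) {
    pair <- generate_grid_outline_pair(base_area = 3e7, linear_scale = sc,
                                       seed = 3L)
    areas <- outline_pair(pair$pre, pair$post)
    expect_lt(abs(areas$post_area / areas$pre_area - sc^2), 0.02 * sc^2)
  }
})

test_that("an oversized silhouette is rejected", {
  expect_error(generate_grid_outline_pair(base_area = 3e7, linear_scale = 4),
               "exceeds the image frame")
})

test_that("transmittance images recover their constructed attenuation", {
  for (att in c(1, 0.75, 0)) {
    g <- generate_grid_transmittance_image(att, seed = 8L)
    got <- relative_transmittance_grid(g$image, g$inner_mask, g$outer_mask)
    expect_lt(abs(as.numeric(got) - 100 * att), 1.5)
  }
})

test_that("dendrite centerlines carry their true tortuosity", {
  dd <- generate_dendrite_stack(depth_extent = 40, plane_interval = 20,
                                path_tortuosity = 1, noise_sd = 0, seed = 6L)
  one <- dd$centerlines[dd$centerlines$dendrite == 1, ]
  expect_equal(tortuosity(one[, c("x_um", "y_um")]), 1, tolerance = 1e-9)
  dd2 <- generate_dendrite_stack(depth_extent = 40, plane_interval = 20,
                                 path_tortuosity = 1.2, noise_sd = 0, seed = 6L)
  two <- dd2$centerlines[dd2$centerlines$dendrite == 1, ]
  expect_equal(tortuosity(two[, c("x_um", "y_um")]), 1.2, tolerance = 0.05)
})

test_that("dendrite stacks honour their SNR schedule", {
  dd <- generate_dendrite_stack(
    depth_extent = 280,
    snr_schedule = data.frame(depth = c(0, 280), snr = c(4, 1.2)),
    noise_sd = 0.5, seed = 12L)
  prof <- snr_profile(dd$volume, dd$centerlines, depths = c(0, 280), seed = 1L)
  expect_lt(abs(prof$snr[prof$depth_um == 0] - 4), 0.4)
  expect_lt(abs(prof$snr[prof$depth_um == 280] - 1.2), 0.12)
})

test_that("fewer than five dendrites per plane is an error", {
  expect_error(generate_dendrite_stack(n_dendrites = 4L), "five")
  expect_error(generate_dendrite_stack(n_dendrites = 40L, image_size = 100L),
               "cannot place")
})
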