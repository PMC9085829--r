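# z-interpolation, Otsu, geodesic active contour and instance separation

test_that("z-interpolation preserves extent and resamples to in-plane spacing", {
  v <- volume_stack(array(runif(10 * 6 * 6), c(10, 6, 6)), c(4, 1, 1))
  iso <- interpolate_isotropic(v)
  expect_equal(unname(voxel_size(iso)), c(1, 1, 1))
  expect_equal(dim(iso), c(37L, 6L, 6L))  # 36 um extent at 1 um steps
})

test_that("interpolating a constant volume is exact", {
  v <- volume_stack(array(7, c(5, 4, 4)), c(4, 1, 1))
  iso <- interpolate_isotropic(v)
  expect_true(all(abs(iso - 7) < 1e-12))
})

test_that("interpolating a linear z-ramp reproduces the closed-form ramp", {
  nz <- 8
  ramp <- array(rep(seq(0, 28, by = 4), times = 25), c(nz, 5, 5))
  v <- volume_stack(ramp, c(4, 1, 1))
  iso <- interpolate_isotropic(v)
  # intensity equals physical z position everywhere on the ramp
  expected <- seq(0, 28, by = 1)
  expect_equal(as.numeric(iso[, 3, 3]), expected, tolerance = 1e-12)
})

test_that("already-isotropic input passes through unchanged", {
  v <- volume_stack(array(runif(64), c(4, 4, 4)), c(2, 2, 2))
  iso <- interpolate_isotropic(v)
  expect_equal(unclass(iso), unclass(v), ignore_attr = TRUE)
})

test_that("a perfectly bimodal volume thresholds between its two values", {
  v <- volume_stack(array(c(rep(20, 400), rep(220, 100)), c(5, 10, 10)),
                    c(1, 1, 1))
  mask <- binarize_otsu(v)
  expect_identical(unclass(mask)[, , ], unclass(v)[, , ] == 220)
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    x <- c(rnorm(n, 80, sample(5:30, 1)), rnorm(n, sample(150:220, 1), 20))
    x <- pmax(x, 0)
    expect_equal(otsu_threshold(x), brute_force_otsu(x), tolerance = 1e-12)
  }
})

test_that("constant volumes have no threshold", {
  expect_error(otsu_threshold(array(3, c(2, 2, 2))), "constant")
})

test_that("dark-foreground flag gives the complementary mask", {
  v <- volume_stack(array(c(rep(20, 300), rep(220, 200)), c(5, 10, 10)),
                    c(1, 1, 1))
  bright <- binarize_otsu(v, "bright")
  dark <- binarize_otsu(v, "dark")
  expect_identical(unclass(bright)[, , ], !unclass(dark)[, , ])
})

gac_fixture <- function() {
  semi <- c(22, 16, 13)
  set.seed(11)
  axes <- test_rotation()
  truth <- rasterize_ellipsoid(c(60, 60, 60), c(1, 1, 1),
                               center = c(30, 30, 30), semi = semi, axes = axes)
  vol <- volume_stack(array(ifelse(truth, 200, 20), dim(truth)), c(1, 1, 1))
  list(vol = vol, truth = truth)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

test_that("the active contour recovers a sharp ellipsoid from a dilated init", {
  fx <- gac_fixture()
  init <- glomorph:::cpp_morph3d(fx$truth, dim(fx$truth), "dilate", 2L)
  out <- refine_geodesic_active_contour(fx$vol, init, iterations = 50)
  expect_gte(jaccard(out, fx$truth), 0.95)
})

test_that("zero iterations return the init mask unchanged", {
  fx <- gac_fixture()
  init <- glomorph:::cpp_morph3d(fx$truth, dim(fx$truth), "dilate", 2L)
  expect_identical(refine_geodesic_active_contour(fx$vol, init,
                                                  iterations = 0), init)
})

test_that("an init on the true boundary is a near fixed point", {
  fx <- gac_fixture()
  out <- refine_geodesic_active_contour(fx$vol, fx$truth, iterations = 50)
  expect_gte(jaccard(out, fx$truth), 0.98)
})

test_that("an empty init mask is an error", {
  fx <- gac_fixture()
  expect_error(refine_geodesic_active_contour(fx$vol, array(FALSE, dim(fx$vol))),
               "empty")
})

test_that("two separated heads yield two labels with accurate centroids", {
  dims <- c(60, 60, 110)
  m <- rasterize_ellipsoid(dims, c(1, 1, 1), c(30, 30, 30), c(18, 18, 18)) |
       rasterize_ellipsoid(dims, c(1, 1, 1), c(80, 30, 30), c(15, 15, 15))
  attr(m, "voxel_size") <- c(1, 1, 1)
  lab <- separate_instances_ellipse_fit(m)
  expect_equal(n_labels(lab), 2L)
  fits <- attr(lab, "fits")
  fits <- fits[fits$kept, ]
  fits <- fits[order(fits$centroid_x), ]
  expect_lt(max(abs(fits$centroid_x - c(30, 80))), 1)
  expect_lt(max(abs(fits$centroid_y - 30)), 1)
  expect_lt(max(abs(fits$centroid_z - 30)), 1)
})

test_that("a single sphere is fitted with semi-axes within 10%", {
  m <- rasterize_ellipsoid(c(50, 50, 50), c(1, 1, 1), c(24, 24, 24),
                           c(16, 16, 16))
  attr(m, "voxel_size") <- c(1, 1, 1)
  lab <- separate_instances_ellipse_fit(m)
  expect_equal(n_labels(lab), 1L)
  fits <- attr(lab, "fits")
  expect_true(all(abs(fits$semi_a / 16 - 1) < 0.1))
  expect_true(all(abs(fits$semi_c / 16 - 1) < 0.1))
})

test_that("an elongated vessel-like segment is rejected by the ellipsoid gates", {
  dims <- c(40, 40, 120)
  m <- array(FALSE, dims)
  m[16:24, 16:24, 5:115] <- TRUE  # 9 x 9 x 111 voxel bar
  attr(m, "voxel_size") <- c(1, 1, 1)
  lab <- separate_instances_ellipse_fit(m, min_peak_height = 3)
  expect_equal(n_labels(lab), 0L)
})

test_that("edge exclusion follows its margin rule", {
  dims <- c(40, 40, 40)
  inner <- rasterize_ellipsoid(dims, c(1, 1, 1), c(20, 20, 20), c(8, 8, 8))
  lab_arr <- array(0L, dims)
  lab_arr[inner] <- 1L
  lab_arr[1, 5, 5] <- 2L  # touches the z = 0 face
  # relabel consecutively: the edge voxel becomes instance 2
  lab <- label_map(lab_arr, c(1, 1, 1))
  expect_equal(n_labels(exclude_edge_objects(lab, 0)), 2L)
  kept <- exclude_edge_objects(lab, 1)
  expect_equal(n_labels(kept), 1L)
  expect_true(all(kept[inner] == 1L))
  expect_error(exclude_edge_objects(lab, 100), "half the stack extent")
})

test_that("glomerulus sampling is deterministic, clamped and uniform", {
  arr <- array(0L, c(4, 4, 50))
  for (k in 1:10) arr[2, 2, 4 * k] <- k
  lab <- label_map(arr, c(1, 1, 1))
  expect_setequal(sample_glomeruli(lab, 10, seed = 1), 1:10)
  big <- label_map(array(rep(1:50, each = 2), c(2, 2, 25)), c(1, 1, 1))
  expect_identical(sample_glomeruli(big, 10, seed = 7),
                   sample_glomeruli(big, 10, seed = 7))
  small <- label_map(array(c(1L, 2L, 3L, 0L), c(1, 2, 2)), c(1, 1, 1))
  expect_warning(ids <- sample_glomeruli(small, 10, seed = 2), "3")
  expect_setequal(ids, 1:3)
  empty <- label_map(array(0L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(sample_glomeruli(empty), "no instances")
})

test_that("end-to-end detection recovers the exact phantom count", {
  spec <- phantom_spec(grid_shape = c(40L, 120L, 120L), voxel_size = c(4, 2, 2),
                       n_glomeruli = 4L, noise_sd = 20, seed = 17L)
  ph <- generate_kidney_phantom(spec)
  lab <- segment_glomeruli(ph$volume, margin = 0)
  expect_equal(n_labels(lab), 4L)
})
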