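# clearing-performance and image-integrity metrics

test_that("a filled disc's outline area matches pi r^2 within 1%", {
  n <- 256
  d <- sqrt(outer((1:n - 128.5)^2, (1:n - 128.5)^2, `+`))
  img <- ifelse(d <= 100, 220, 20)
  out <- extract_outline_area(img)
  expect_rel_equal(out$area, pi * 100^2, 0.01)
  expect_identical(extract_outline_area(img)$area, out$area)
  expect_gt(nrow(out$polygon), 10)
})

test_that("linear expansion is the square root of the area ratio", {
  expect_equal(linear_expansion(list(pre_area = 5, post_area = 5)), 1)
  expect_equal(linear_expansion(list(pre_area = 2, post_area = 8)), 2)
  # shrinkage regime: a 1.9% area loss is a ~0.95% linear shrinkage
  le <- linear_expansion(list(pre_area = 1, post_area = 0.981))
  expect_equal(le, sqrt(0.981), tolerance = 1e-12)
  expect_equal(100 * (1 - le), 0.9545, tolerance = 1e-3)
  expect_equal(area_change_ratio(list(pre_area = 4, post_area = 8)), 2)
  expect_error(linear_expansion(list(pre_area = 0, post_area = 2)), "positive")
})

test_that("expansion obeys the square and composition laws", {
  a <- 3.21; b <- 5.43; cc <- 1.77
  expect_lt(abs(linear_expansion(list(pre_area = a, post_area = b))^2 -
                area_change_ratio(list(pre_area = a, post_area = b))), 1e-9)
  lab <- linear_expansion(list(pre_area = a, post_area = b))
  lbc <- linear_expansion(list(pre_area = b, post_area = cc))
  lac <- linear_expansion(list(pre_area = a, post_area = cc))
  expect_lt(abs(lab * lbc - lac), 1e-9)
})

test_that("relative grid transmittance behaves at the identities", {
  img <- matrix(100, 20, 20)
  inner <- matrix(FALSE, 20, 20); inner[6:15, 6:15] <- TRUE
  outer_m <- !inner
  expect_equal(as.numeric(relative_transmittance_grid(img, inner, outer_m)), 100)
  img2 <- img; img2[inner] <- 0
  expect_equal(as.numeric(relative_transmittance_grid(img2, inner, outer_m)), 0)
  img3 <- img; img3[inner] <- 60
  expect_equal(as.numeric(relative_transmittance_grid(img3, inner, outer_m)), 60)
  # gain invariance
  expect_equal(as.numeric(relative_transmittance_grid(img3 * 7, inner, outer_m)), 60)
  # bright-field convention: dark grid lines on a bright background
  bf <- matrix(200, 20, 20)
  in_lines <- matrix(FALSE, 20, 20); in_lines[8:12, 8:12] <- TRUE
  out_lines <- matrix(FALSE, 20, 20); out_lines[2:4, 2:18] <- TRUE
  bf[in_lines] <- 120  # seen through the sample: blocks less light
  bf[out_lines] <- 50
  expect_equal(as.numeric(relative_transmittance_grid(bf, in_lines, out_lines,
                                                      invert = TRUE)),
               100 * 80 / 150)
  expect_error(relative_transmittance_grid(img * 0, inner, outer_m), "zero")
  expect_error(relative_transmittance_grid(img, inner, inner), "disjoint")
})

test_that("spectral transmittance is the elementwise sample/blank percent", {
  wl <- seq(400, 800, by = 50)
  blank <- data.frame(wavelength = wl, value = rep(2, length(wl)))
  expect_true(all(spectral_transmittance(blank, blank)$transmittance_pct == 100))
  zero <- data.frame(wavelength = wl, value = rep(0, length(wl)))
  expect_true(all(spectral_transmittance(zero, blank)$transmittance_pct == 0))
  half <- data.frame(wavelength = wl, value = rep(1, length(wl)))
  expect_true(all(spectral_transmittance(half, blank)$transmittance_pct == 50))
  off <- data.frame(wavelength = wl + 1, value = rep(1, length(wl)))
  expect_error(spectral_transmittance(off, blank), "wavelength")
  expect_error(spectral_transmittance(blank, zero), "zero")
})

test_that("fluorescence retention is day-0 normalized after background subtraction", {
  s <- data.frame(day = c(0, 2), signal = c(100, 60), background = c(20, 20))
  r <- normalized_fluorescence(s)
  expect_equal(r$retention, c(1, 0.5))
  const <- data.frame(day = 0:4, signal = 70 + 0:4, background = 20 + 0:4)
  expect_true(all(normalized_fluorescence(const)$retention == 1))
  bad <- data.frame(day = c(0, 1), signal = c(10, 50), background = c(20, 20))
  expect_error(normalized_fluorescence(bad), "positive")
})

test_that("the SNR estimator reads constructed core/flank ratios", {
  # one straight horizontal dendrite, rectangular profile sized to the core
  img <- matrix(100, 60, 60)
  img[28:34, ] <- 400  # ~7 px wide band at y ~ 30
  stack <- volume_stack(array(img, c(1, 60, 60)), c(1, 1, 1))
  cl <- tibble::tibble(dendrite = rep(1:5, each = 60), z_um = 0,
                       x_um = rep(0:59, 5), y_um = rep(30, 300))
  prof <- snr_profile(stack, cl, depths = 0, n_dendrites = 5, seed = 1)
  expect_lt(abs(prof$snr - 4), 0.25)
  flat <- volume_stack(array(100, c(1, 60, 60)), c(1, 1, 1))
  prof0 <- snr_profile(flat, cl, depths = 0, n_dendrites = 5, seed = 1)
  expect_equal(prof0$snr, 1)
})

test_that("SNR profiles fall with monotonically decreasing contrast schedules", {
  dd <- generate_dendrite_stack(
    depth_extent = 280,
    snr_schedule = data.frame(depth = c(0, 140, 280), snr = c(4, 2.5, 1.2)),
    noise_sd = 1, seed = 3L)
  prof <- snr_profile(dd$volume, dd$centerlines,
                      depths = seq(0, 280, by = 140), seed = 2L)
  expect_true(all(diff(prof$snr) < 0))
})

test_that("too few dendrites at a depth is an error", {
  flat <- volume_stack(array(100, c(1, 20, 20)), c(1, 1, 1))
  cl <- tibble::tibble(dendrite = rep(1:3, each = 20), z_um = 0,
                       x_um = rep(0:19, 3), y_um = rep(10, 60))
  expect_error(snr_profile(flat, cl, depths = 0), "need 5")
})

test_that("tortuosity is arc length over chord", {
  expect_equal(tortuosity(cbind(c(0, 10), c(0, 0))), 1)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(cos(th), sin(th))
  expect_rel_equal(tortuosity(semi), pi / 2, 0.001)
  set.seed(9)
  for (i in 1:10) {
    p <- matrix(rnorm(30), ncol = 3)
    expect_gte(tortuosity(p), 1 - 1e-9)
  }
  expect_error(tortuosity(rbind(c(0, 0), c(0, 0))), "coincide")
})

test_that("rigid alignment recovers constructed shifts and rotations", {
  set.seed(10)
  base <- matrix(0, 96, 96)
  for (i in 1:12) {
    r <- sample(15:80, 1); cc <- sample(15:80, 1)
    base[r + (-2:2), cc + (-2:2)] <- runif(1, 100, 200)
  }
  base <- glomorph:::gauss_filter2d(base, 1.5, 9)
  self <- align_rigid(base, base, rotations = -3:3)
  expect_equal(self$angle, 0)
  expect_equal(self$shift, c(0, 0))
  shifted <- glomorph:::shift_image(base, c(5, -3))
  al <- align_rigid(base, shifted, rotations = -3:3)
  expect_equal(al$shift, c(-5, 3))  # the shift that re-aligns b onto a
  expect_gt(glomorph:::ncc(base, al$aligned), 0.99)
  rot <- glomorph:::rotate_image(base, -10)
  alr <- align_rigid(base, rot, rotations = seq(-15, 15, by = 1))
  expect_lte(abs(alr$angle - 10), 1)
})

test_that("binary SSIM hits its identities and anticorrelation", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64)
  img <- glomorph:::gauss_filter2d(img, 2, 11) > 0.5
  expect_equal(ssim_binary(img * 1, img * 1), 1, tolerance = 1e-12)
  expect_lt(ssim_binary(img * 1, 1 - img), 0)
  expect_error(ssim_binary(img * 1, matrix(0, 3, 3)), "identical dimensions")
})

test_that("the SSIM map equals the windowed formula evaluated directly", {
  set.seed(6)
  a <- (matrix(runif(31 * 31), 31) > 0.5) * 1
  b <- (matrix(runif(31 * 31), 31) > 0.4) * 1
  # independent oracle for the centre pixel: explicit Gaussian window sums
  r <- 5
  w1 <- exp(-((-r:r)^2) / (2 * 1.5^2)); w1 <- w1 / sum(w1)
  w <- outer(w1, w1)
  win_a <- a[11:21, 11:21]; win_b <- b[11:21, 11:21]
  mu_a <- sum(w * win_a); mu_b <- sum(w * win_b)
  va <- sum(w * win_a^2) - mu_a^2; vb <- sum(w * win_b^2) - mu_b^2
  cab <- sum(w * win_a * win_b) - mu_a * mu_b
  C1 <- 1e-4; C2 <- 9e-4
  oracle <- (2 * mu_a * mu_b + C1) * (2 * cab + C2) /
            ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  # recompute the implementation's map value at the same centre pixel
  mu_am <- glomorph:::gauss_filter2d(a, 1.5, 11)
  mu_bm <- glomorph:::gauss_filter2d(b, 1.5, 11)
  vam <- glomorph:::gauss_filter2d(a * a, 1.5, 11) - mu_am^2
  vbm <- glomorph:::gauss_filter2d(b * b, 1.5, 11) - mu_bm^2
  cabm <- glomorph:::gauss_filter2d(a * b, 1.5, 11) - mu_am * mu_bm
  got <- ((2 * mu_am[16, 16] * mu_bm[16, 16] + C1) * (2 * cabm[16, 16] + C2)) /
         ((mu_am[16, 16]^2 + mu_bm[16, 16]^2 + C1) *
          (vam[16, 16] + vbm[16, 16] + C2))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("ratio metrics are invariant to uniform intensity gain", {
  s <- data.frame(day = c(0, 3), signal = c(100, 60), background = c(20, 20))
  s2 <- transform(s, signal = signal * 3, background = background * 3)
  expect_equal(normalized_fluorescence(s)$retention,
               normalized_fluorescence(s2)$retention)
  p <- cbind(c(0, 3, 7), c(0, 4, 1))
  expect_equal(tortuosity(p), tortuosity(p * 5))
})
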