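#' Synthetic bright-field outline pair on a printed grid
#'
#' Emulates the pre-/post-clearing photographs used to measure sample size
#' change: a bright tissue silhouette (an ellipse of the requested area) on a
#' dark background overprinted with a faint reference grid. The post image
#' holds the same silhouette with its linear dimensions scaled by
#' `linear_scale`, so the measured area ratio is `linear_scale^2` up to
#' rasterization.
#'
#' @param base_area Pre-clearing silhouette area in um^2.
#' @param linear_scale Linear size factor of the post image (> 0).
#' @param grid_pitch Grid period in um (1.5 mm grid paper by default).
#' @param image_size Image side in pixels.
#' @param pixel_size Pixel pitch in um.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with matrices `pre` and `post` (attribute `pixel_size_um`).
#' @export
generate_grid_outline_pair <- function(base_area, linear_scale,
                                       grid_pitch = 1500, image_size = 384L,
                                       pixel_size = 50, noise_sd = 2,
                                       seed = 1L) {
  if (linear_scale <= 0) abort("`linear_scale` must be positive.")
  aspect <- 1.25
  rx <- sqrt(base_area * aspect / pi)
  ry <- rx / aspect
  half <- image_size * pixel_size / 2
  if (max(rx, ry) * max(1, linear_scale) > 0.9 * half)
    abort("silhouette exceeds the image frame; enlarge `image_size`.")
  with_seed(seed, {
    render <- function(scale) {
      co <- (seq_len(image_size) - (image_size + 1) / 2) * pixel_size
      gx <- matrix(co, image_size, image_size, byrow = TRUE)
      gy <- matrix(co, image_size, image_size)
      img <- matrix(20, image_size, image_size)
      on_grid <- (abs(gx) %% grid_pitch < pixel_size) |
                 (abs(gy) %% grid_pitch < pixel_size)
      img[on_grid] <- 60
      f <- sqrt((gx / (rx * scale))^2 + (gy / (ry * scale))^2)
      img[f <= 1] <- 220
      img <- img + matrix(rnorm(image_size^2, 0, noise_sd), image_size)
      attr(img, "pixel_size_um") <- pixel_size
      img
    }
    list(pre = render(1), post = render(linear_scale))
  })
}

#' Synthetic transmittance grid image
#'
#' A bright reference grid on a dark background with a central "sample"
#' region through which the grid is seen attenuated: inner grid line
#' intensity equals `attenuation` times the outer line intensity before
#' noise. Masks of inner and outer grid-line pixels are returned alongside,
#' ready for [relative_transmittance_grid()].
#'
#' @param attenuation Fraction in \[0, 1\].
#' @param image_size,grid_pitch,line_width Geometry in pixels.
#' @param line_intensity,background Intensities in arbitrary units.
#' @param noise_sd Additive Gaussian noise SD.
#' @param inner_fraction Side fraction of the central sample region.
#' @param seed Integer seed.
#' @return List with `image`, logical `inner_mask` and `outer_mask`, and the
#'   requested `attenuation`.
#' @export
generate_grid_transmittance_image <- function(attenuation, image_size = 256L,
                                              grid_pitch = 32L, line_width = 2L,
                                              line_intensity = 200,
                                              background = 0, noise_sd = 1,
                                              inner_fraction = 0.4,
                                              seed = 1L) {
  if (attenuation < 0 || attenuation > 1)
    abort("`attenuation` must lie in [0, 1].")
  with_seed(seed, {
    px <- seq_len(image_size)
    on_line_1d <- (px - 1L) %% grid_pitch < line_width
    lines <- outer(on_line_1d, on_line_1d, `|`)
    half <- image_size / 2
    inner_half <- inner_fraction * image_size / 2
    inside <- outer(abs(px - half) <= inner_half,
                    abs(px - half) <= inner_half, `&`)
    img <- matrix(background, image_size, image_size)
    img[lines & !inside] <- line_intensity
    img[lines & inside] <- attenuation * line_intensity
    img <- img + matrix(rnorm(image_size^2, 0, noise_sd), image_size)
    list(image = img, inner_mask = lines & inside, outer_mask = lines & !inside,
         attenuation = attenuation)
  })
}

#' Synthetic dendrite stack with a depth-dependent contrast schedule
#'
#' Emulates the confocal depth series used for SNR-versus-depth curves:
#' planes at fixed depth intervals, each carrying several bright sinuous
#' dendrites on a uniform background, with per-depth dendrite/background
#' contrast following `snr_schedule` (linearly interpolated between scheduled
#' depths). Centerlines are returned with their true arc length, so the
#' ground-truth tortuosity of every dendrite is known.
#'
#' @param depth_extent Total imaged depth in um.
#' @param snr_schedule Data frame with columns `depth` (um) and `snr`
#'   (target dendrite/background intensity ratio).
#' @param path_tortuosity Target arc/chord ratio of the sinusoidal
#'   centerlines (>= 1).
#' @param n_dendrites Dendrites per plane (at least 5).
#' @param plane_interval Depth spacing of planes in um.
#' @param image_size In-plane image side in pixels (1 um pixels).
#' @param dendrite_radius Dendrite radius in um.
#' @param background Background intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param profile_halfwidth Half-length (um) of the perpendicular sampling
#'   line of [snr_profile()]; the dendrite intensity is calibrated so that
#'   the core/flank estimator with this geometry recovers the scheduled SNR
#'   exactly (the estimator's core window is wider than the dendrite, so an
#'   uncalibrated peak ratio would under-read).
#' @param seed Integer seed.
#' @return List with `volume` (a [volume_stack()], spacing
#'   `(plane_interval, 1, 1)`) and `centerlines` (tibble: `dendrite`, `z_um`,
#'   `x_um`, `y_um` ordered along each path).
#' @export
generate_dendrite_stack <- function(depth_extent = 280,
                                    snr_schedule = data.frame(
                                      depth = c(0, depth_extent),
                                      snr = c(4, 1.2)),
                                    path_tortuosity = 1.05, n_dendrites = 6L,
                                    plane_interval = 20, image_size = 160L,
                                    dendrite_radius = 3.3, background = 100,
                                    noise_sd = 2, profile_halfwidth = 10,
                                    seed = 1L) {
  if (n_dendrites < 5L)
    abort("at least five dendrites per plane are required for SNR sampling.")
  if (any(snr_schedule$depth < 0) || any(snr_schedule$depth > depth_extent))
    abort("`snr_schedule` depths must lie within the depth extent.")
  spacing_px <- image_size / (n_dendrites + 1)
  if (spacing_px < 6 * dendrite_radius)
    abort(sprintf("cannot place %d separated dendrites in a %d px plane.",
                  n_dendrites, image_size))
  with_seed(seed, {
    depths <- seq(0, depth_extent, by = plane_interval)
    nz <- length(depths)
    vol <- array(background, c(nz, image_size, image_size))
    cl <- list()
    did <- 0L
    wavelength <- image_size / 1.5
    amp <- sinusoid_amplitude(path_tortuosity, wavelength)
    xs <- seq(0, image_size - 1)
    # core/flank coverage fractions of the soft tube under the sampler
    # geometry, used to solve for the intensity that makes the estimator
    # read exactly the scheduled SNR
    t <- seq(-profile_halfwidth, profile_halfwidth, by = 0.05)
    cov_t <- clamp(0.5 - (abs(t) - dendrite_radius), 0, 1)
    core <- abs(t) <= profile_halfwidth / 3
    c_frac <- mean(cov_t[core])
    f_frac <- mean(cov_t[!core])
    for (zi in seq_len(nz)) {
      snr_z <- approx(snr_schedule$depth, snr_schedule$snr, xout = depths[zi],
                      rule = 2)$y
      if (c_frac - snr_z * f_frac <= 0)
        abort("dendrite too wide for this SNR schedule; reduce dendrite_radius.")
      intensity <- background + background * (snr_z - 1) /
        (c_frac - snr_z * f_frac)
      plane <- vol[zi, , ]
      # one phase per plane: parallel curves keep their lateral spacing, so
      # no dendrite ever wanders into a neighbour's flank window
      phase <- runif(1, 0, 2 * pi)
      for (k in seq_len(n_dendrites)) {
        did <- did + 1L
        y0 <- spacing_px * k
        ys <- y0 + amp * sin(2 * pi * xs / wavelength + phase)
        cl[[did]] <- tibble(dendrite = did, z_um = depths[zi],
                            x_um = xs, y_um = ys)
        plane <- draw_tube(plane, xs, ys, dendrite_radius,
                           intensity, background)
      }
      vol[zi, , ] <- plane
    }
    if (noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, noise_sd), dim(vol))
    list(volume = volume_stack(pmax(vol, 0), c(plane_interval, 1, 1),
                               provenance = "dendrite phantom"),
         centerlines = dplyr::bind_rows(cl))
  })
}

# amplitude giving a target arc/chord ratio for y = A sin(2 pi x / lambda)
sinusoid_amplitude <- function(tortuosity, wavelength) {
  if (tortuosity <= 1) return(0)
  arc_ratio <- function(a) {
    x <- seq(0, wavelength, length.out = 400)
    y <- a * sin(2 * pi * x / wavelength)
    sum(sqrt(diff(x)^2 + diff(y)^2)) / wavelength
  }
  lo <- 0
  hi <- wavelength
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (arc_ratio(mid) < tortuosity) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# paint a soft-edged tube of the given half-width along a sampled curve
draw_tube <- function(plane, xs, ys, radius, intensity, background) {
  n <- nrow(plane)
  r_ext <- ceiling(radius + 1)
  for (i in seq_along(xs)) {
    xc <- xs[i] + 1
    yc <- ys[i] + 1
    xr <- max(1, floor(xc - r_ext)):min(n, ceiling(xc + r_ext))
    yr <- max(1, floor(yc - r_ext)):min(n, ceiling(yc + r_ext))
    d <- sqrt(outer((yr - yc)^2, (xr - xc)^2, `+`))
    cov <- clamp(0.5 - (d - radius), 0, 1)
    val <- background + (intensity - background) * cov
    plane[yr, xr] <- pmax(plane[yr, xr], val)
  }
  plane
}
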