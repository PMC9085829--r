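#' Outline area of a tissue silhouette
#'
#' Thresholds a bright-field image with Otsu's method, keeps the largest
#' connected foreground component, and returns its pixel area in calibrated
#' units together with the ordered boundary polygon (extracted as the 0.5
#' contour of the component mask).
#'
#' @param image Numeric matrix; attribute `pixel_size_um` (or the
#'   `pixel_size` argument) calibrates areas to um^2, else px^2.
#' @param pixel_size Pixel pitch in um (overrides the attribute).
#' @return List with `area`, `polygon` (two-column matrix, calibrated
#'   units) and `pixel_size`.
#' @export
extract_outline_area <- function(image, pixel_size = NULL) {
  ps <- pixel_size %||% attr(image, "pixel_size_um") %||% 1
  thr <- otsu_threshold(image)
  mask <- image > thr
  if (!any(mask)) abort("no foreground after Otsu thresholding.")
  lab <- cpp_label3d(array(mask, c(1, nrow(image), ncol(image))),
                     c(1L, nrow(image), ncol(image)))
  lab <- lab[1, , ]
  counts <- tabulate(lab[lab > 0])
  big <- which.max(counts)
  comp <- lab == big
  cl <- grDevices::contourLines(x = seq_len(nrow(comp)),
                                y = seq_len(ncol(comp)),
                                z = comp * 1, levels = 0.5)
  poly <- if (length(cl)) {
    lens <- vapply(cl, function(s) length(s$x), numeric(1))
    s <- cl[[which.max(lens)]]
    cbind(x = s$x * ps, y = s$y * ps)
  } else matrix(numeric(), 0, 2)
  list(area = sum(comp) * ps^2, polygon = poly, pixel_size = ps)
}

#' Linear expansion and area change of an outline pair
#'
#' `area_change_ratio()` is the post/pre area ratio; `linear_expansion()` is
#' its square root, the per-axis size factor: 1 means no size change, values
#' below 1 shrinkage, above 1 expansion.
#'
#' @param pair List with numeric `pre_area` and `post_area` (same units),
#'   e.g. built from two [extract_outline_area()] results.
#' @return A unitless factor.
#' @export
linear_expansion <- function(pair) {
  check_outline_pair(pair)
  sqrt(pair$post_area / pair$pre_area)
}

#' @rdname linear_expansion
#' @export
area_change_ratio <- function(pair) {
  check_outline_pair(pair)
  pair$post_area / pair$pre_area
}

check_outline_pair <- function(pair) {
  if (is.null(pair$pre_area) || is.null(pair$post_area) ||
      !is.finite(pair$pre_area) || !is.finite(pair$post_area) ||
      pair$pre_area <= 0 || pair$post_area <= 0)
    abort("outline pair must carry positive `pre_area` and `post_area`.")
}

#' @rdname linear_expansion
#' @param pre,post Images or [extract_outline_area()] results.
#' @param ... Passed to [extract_outline_area()].
#' @export
outline_pair <- function(pre, post, ...) {
  area_of <- function(x) {
    if (is.list(x) && !is.null(x$area)) x$area
    else extract_outline_area(x, ...)$area
  }
  list(pre_area = area_of(pre), post_area = area_of(post))
}

#' Relative transmittance from a grid image
#'
#' The mean intensity of the grid seen through the sample (inner mask)
#' normalized to the grid outside the sample (outer mask), as a percentage.
#' Values may exceed 100 slightly through noise; the overshoot is clipped
#' and reported in the `clipped_by` attribute.
#'
#' @param image Numeric matrix.
#' @param inner_mask,outer_mask Disjoint nonempty logical masks of inner and
#'   outer grid-line pixels.
#' @param invert Invert the image first (`max - image`), for bright-field
#'   material where the grid is dark.
#' @return Percent transmittance in \[0, 100\].
#' @export
relative_transmittance_grid <- function(image, inner_mask, outer_mask,
                                        invert = FALSE) {
  if (!any(inner_mask) || !any(outer_mask))
    abort("inner and outer masks must be nonempty.")
  if (any(inner_mask & outer_mask))
    abort("inner and outer masks must be disjoint.")
  if (invert) image <- max(image) - image
  outer_mean <- mean(image[outer_mask])
  if (abs(outer_mean) < 1e-12) abort("outer grid mean intensity is zero.")
  raw <- 100 * mean(image[inner_mask]) / outer_mean
  out <- clamp(raw, 0, 100)
  attr(out, "clipped_by") <- raw - out
  out
}

#' Spectral transmittance against a blank scan
#'
#' Elementwise sample/blank ratio as percent over a shared wavelength grid,
#' as produced by a spectrophotometer scan (typically 400-800 nm).
#'
#' @param sample_scan,blank_scan Data frames with columns `wavelength` and
#'   `value`, on identical wavelength grids.
#' @return Tibble with `wavelength` and `transmittance_pct`.
#' @export
spectral_transmittance <- function(sample_scan, blank_scan) {
  if (!identical(as.numeric(sample_scan$wavelength),
                 as.numeric(blank_scan$wavelength)))
    abort("sample and blank scans must share the same wavelength grid.")
  if (any(blank_scan$value == 0)) abort("blank scan contains zero values.")
  tibble(wavelength = as.numeric(sample_scan$wavelength),
         transmittance_pct = 100 * sample_scan$value / blank_scan$value)
}

#' Fluorescence retention normalized to day 0
#'
#' Background-subtracted signal per day divided by the background-subtracted
#' signal on day 0, so day 0 is exactly 1 and a value of 0.9 after several
#' days means 90% retention.
#'
#' @param series Data frame with columns `day`, `signal`, `background`.
#' @return Tibble with `day` and `retention` (day 0 first).
#' @export
normalized_fluorescence <- function(series) {
  if (!all(c("day", "signal", "background") %in% names(series)))
    abort("`series` needs columns day, signal, background.")
  i0 <- which(series$day == 0)
  if (length(i0) != 1) abort("`series` must contain exactly one day-0 entry.")
  net0 <- series$signal[i0] - series$background[i0]
  if (net0 <= 0) abort("day-0 net signal must be positive.")
  ord <- order(series$day)
  tibble(day = series$day[ord],
         retention = (series$signal[ord] - series$background[ord]) / net0)
}

#' Depth-resolved signal-to-noise profile
#'
#' For each requested depth, `n_dendrites` dendrites are sampled at random
#' from the centerlines crossing that plane; for each, an intensity profile
#' is read along a line perpendicular to the local dendrite axis, and the
#' per-dendrite SNR is the mean over the central core third of the profile
#' divided by the mean over the two outer flank thirds (the adjacent
#' surrounding area). The reported value per depth is the mean over the
#' sampled dendrites. Set `definition = "contrast"` for the
#' (core - flank)/flank variant.
#'
#' @param stack A [volume_stack()] of dendrite planes.
#' @param centerlines Tibble as from [generate_dendrite_stack()]:
#'   `dendrite`, `z_um`, `x_um`, `y_um`.
#' @param depths Depths (um) to evaluate; must coincide with stack planes.
#' @param n_dendrites Dendrites sampled per depth (default 5).
#' @param seed Integer seed for the per-depth sampling.
#' @param profile_halfwidth Half-length of the perpendicular line in um
#'   (about 2.5 dendrite widths).
#' @param definition `"ratio"` (default) or `"contrast"`.
#' @return A `depth_profile` tibble: `depth_um`, `snr`.
#' @export
snr_profile <- function(stack, centerlines, depths, n_dendrites = 5L,
                        seed = 1L, profile_halfwidth = 10,
                        definition = c("ratio", "contrast")) {
  definition <- match.arg(definition)
  vs <- voxel_size(stack)
  z_planes <- (seq_len(dim(stack)[1]) - 1) * vs[1]
  rows <- with_seed(seed, purrr::map_dfr(depths, function(dep) {
    zi <- which(abs(z_planes - dep) < vs[1] / 2)
    if (length(zi) != 1)
      abort(sprintf("no stack plane at depth %g um.", dep))
    cz <- centerlines[abs(centerlines$z_um - z_planes[zi]) < 1e-9, ]
    ids <- unique(cz$dendrite)
    if (length(ids) < n_dendrites)
      abort(sprintf("only %d dendrite(s) cross depth %g um; need %d.",
                    length(ids), dep, n_dendrites))
    pick <- sample(ids, n_dendrites)
    snr_i <- vapply(pick, function(id) {
      path <- cz[cz$dendrite == id, ]
      mid <- nrow(path) %/% 2
      tang <- c(path$x_um[mid + 1] - path$x_um[mid - 1],
                path$y_um[mid + 1] - path$y_um[mid - 1])
      perp <- normalize2(c(-tang[2], tang[1]))
      t <- seq(-profile_halfwidth, profile_halfwidth, by = min(vs[2:3]) / 2)
      px <- path$x_um[mid] + t * perp[1]
      py <- path$y_um[mid] + t * perp[2]
      prof <- bilinear_plane(stack[zi, , ], py / vs[2] + 1, px / vs[3] + 1)
      n <- length(prof)
      third <- n %/% 3
      core <- mean(prof[(third + 1):(n - third)])
      flank <- mean(prof[c(seq_len(third), (n - third + 1):n)])
      if (definition == "ratio") core / flank else (core - flank) / flank
    }, numeric(1))
    tibble(depth_um = dep, snr = mean(snr_i))
  }))
  structure(rows, class = c("depth_profile", class(rows)),
            definition = definition)
}

normalize2 <- function(v) v / sqrt(sum(v^2))

# bilinear sampling of a matrix at fractional (row, col) positions
bilinear_plane <- function(m, r, cc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- clamp(r, 1, nr); cc <- clamp(cc, 1, nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(cc), nc - 1)
  fr <- r - r0; fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Tortuosity of a path
#'
#' The arc length `d` of an ordered polyline divided by the straight
#' distance `D` between its endpoints; 1 for a straight segment, pi/2 for a
#' semicircle.
#'
#' @param path Matrix or data frame of ordered points (2 or 3 columns).
#' @return `d / D`, always >= 1 up to numerical precision.
#' @export
tortuosity <- function(path) {
  p <- as.matrix(path)
  if (nrow(p) < 2) abort("`path` needs at least two points.")
  ends <- p[nrow(p), ] - p[1, ]
  D <- sqrt(sum(ends^2))
  if (D < 1e-12) abort("path endpoints coincide; tortuosity undefined.")
  d <- sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  d / D
}

#' Rigid alignment of two images
#'
#' Coarse-to-fine rigid registration: for each candidate rotation the
#' translation is found at the peak of the FFT cross-correlation, and the
#' pose with the best normalized cross-correlation wins. If no pose reaches
#' `score_floor`, a warning is raised and the identity transform returned.
#'
#' @param image_a Reference image (matrix).
#' @param image_b Moving image, same size.
#' @param rotations Candidate rotations in degrees.
#' @param score_floor Minimum acceptable normalized cross-correlation.
#' @return List with `angle` (deg), `shift` (rows, cols), `score` and
#'   `aligned` (image_b resampled onto image_a).
#' @export
align_rigid <- function(image_a, image_b, rotations = seq(-15, 15, by = 1),
                        score_floor = 0.2) {
  if (!identical(dim(image_a), dim(image_b)))
    abort("images must have identical dimensions.")
  a0 <- image_a - mean(image_a)
  best <- list(score = -Inf)
  for (th in rotations) {
    rb <- rotate_image(image_b, th)
    sh <- xcorr_peak_shift(a0, rb - mean(rb))
    al <- shift_image(rb, sh)
    sc <- ncc(image_a, al)
    if (sc > best$score)
      best <- list(angle = th, shift = sh, score = sc, aligned = al)
  }
  if (best$score < score_floor) {
    warn(sprintf("no rigid pose reached correlation %.2f; returning identity.",
                 score_floor))
    return(list(angle = 0, shift = c(0, 0), score = ncc(image_a, image_b),
                aligned = image_b))
  }
  best
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(0)
  sum(a * b) / den
}

# rotation about the image centre with bilinear resampling, edge fill = mean
rotate_image <- function(m, degrees) {
  if (abs(degrees) < 1e-12) return(m)
  th <- degrees * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cr
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  rs <- cos(th) * r - sin(th) * cl + cr
  cs <- sin(th) * r + cos(th) * cl + cc
  out <- matrix(mean(m), nr, nc)
  ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  out[ok] <- bilinear_plane(m, rs[ok], cs[ok])
  out
}

# integer translation (rows, cols) maximizing circular cross-correlation
xcorr_peak_shift <- function(a, b) {
  X <- fft(a) * Conj(fft(b))
  cc <- Re(fft(X, inverse = TRUE))
  peak <- which.max(cc)
  pr <- (peak - 1) %% nrow(a)
  pc <- (peak - 1) %/% nrow(a)
  if (pr > nrow(a) / 2) pr <- pr - nrow(a)
  if (pc > ncol(a) / 2) pc <- pc - ncol(a)
  c(pr, pc)
}

shift_image <- function(m, shift) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(mean(m), nr, nc)
  src_r <- seq_len(nr) - shift[1]
  src_c <- seq_len(nc) - shift[2]
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Structural similarity of two binarized images
#'
#' Both images are binarized with Otsu's threshold, then the standard SSIM
#' index is computed with its default parameters (11 x 11 Gaussian window of
#' sigma 1.5, stability constants K1 = 0.01 and K2 = 0.03, dynamic range 1)
#' and averaged over the map. Identical images give 1; complementary binary
#' images give a strongly negative index.
#'
#' @param image_a,image_b Numeric matrices of equal size.
#' @param binarize Apply Otsu binarization first (the intended use); set to
#'   `FALSE` to evaluate SSIM on the raw intensities scaled to \[0, 1\].
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim_binary <- function(image_a, image_b, binarize = TRUE) {
  if (!identical(dim(image_a), dim(image_b)))
    abort("images must have identical dimensions.")
  prep <- function(m) {
    if (binarize) {
      if (diff(range(m)) == 0) return(matrix(1, nrow(m), ncol(m)))
      (m > otsu_threshold(m)) * 1
    } else {
      rng <- range(m)
      if (diff(rng) == 0) matrix(0, nrow(m), ncol(m))
      else (m - rng[1]) / diff(rng)
    }
  }
  a <- prep(image_a)
  b <- prep(image_b)
  C1 <- 0.01^2
  C2 <- 0.03^2
  mu_a <- gauss_filter2d(a, 1.5, 11)
  mu_b <- gauss_filter2d(b, 1.5, 11)
  va <- gauss_filter2d(a * a, 1.5, 11) - mu_a^2
  vb <- gauss_filter2d(b * b, 1.5, 11) - mu_b^2
  cab <- gauss_filter2d(a * b, 1.5, 11) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
              ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(ssim_map)
}
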