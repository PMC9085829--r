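#' Specification of a synthetic kidney phantom
#'
#' Describes one synthetic light-sheet stack of a DiI-labelled kidney
#' region: bright ellipsoidal glomerular heads joined by bright cylindrical
#' necks to a dimmer random vascular tree, rendered on an anisotropic grid
#' (default 4 um plane interval, 1 um in-plane), blurred by an isotropic
#' Gaussian point-spread function and corrupted by optional Poisson plus
#' additive Gaussian noise. Defaults emulate a mouse kidney at light-sheet
#' scale: glomerular head semi-axes of about 30 um (tuft diameter 60-80 um),
#' arteriolar neck radius of about 7 um, and a bright membrane dye signal
#' well above the parenchymal background. Contrast values are free
#' parameters of the phantom, not calibrated measurements.
#'
#' @param grid_shape Voxel counts `(z, y, x)`.
#' @param voxel_size Spacing `(z, y, x)` in um; the default mirrors z-stacks
#'   at 4 um intervals with 1 um pixels.
#' @param n_glomeruli Number of glomeruli to place (0 gives vessels only).
#' @param head_semi_axes_dist,neck_radius_dist,neck_length_dist Mean and SD
#'   (um) of the Gaussian draws for head ellipsoid semi-axes, neck radius and
#'   neck length.
#' @param head_intensity,vessel_intensity,background_intensity Arbitrary
#'   units; heads and necks share `head_intensity`.
#' @param psf_sigma Isotropic Gaussian PSF sigma in um, applied on the fine
#'   isotropic grid before z-decimation.
#' @param noise_sd Additive Gaussian noise SD.
#' @param poisson_noise Apply Poisson (shot) noise before the Gaussian term.
#' @param vessel_density Target vessel volume fraction of the stack.
#' @param edge_margin Minimum clearance (um) between a head surface and any
#'   stack face.
#' @param seed Integer RNG seed; equal specs with equal seeds render
#'   bit-identical phantoms.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(50L, 180L, 180L),
                         voxel_size = c(4, 1, 1),
                         n_glomeruli = 3L,
                         head_semi_axes_dist = c(mean = 30, sd = 3),
                         neck_radius_dist = c(mean = 7, sd = 0.7),
                         neck_length_dist = c(mean = 30, sd = 4),
                         head_intensity = 3000,
                         vessel_intensity = 400,
                         background_intensity = 100,
                         psf_sigma = 1,
                         noise_sd = 50,
                         poisson_noise = FALSE,
                         vessel_density = 0.01,
                         edge_margin = 10,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size = as.numeric(voxel_size),
               n_glomeruli = as.integer(n_glomeruli),
               head_semi_axes_dist = dist2(head_semi_axes_dist),
               neck_radius_dist = dist2(neck_radius_dist),
               neck_length_dist = dist2(neck_length_dist),
               head_intensity = head_intensity,
               vessel_intensity = vessel_intensity,
               background_intensity = background_intensity,
               psf_sigma = psf_sigma, noise_sd = noise_sd,
               poisson_noise = isTRUE(poisson_noise),
               vessel_density = vessel_density,
               edge_margin = edge_margin, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

dist2 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 2) abort("distributions are given as c(mean, sd).")
  setNames(x, c("mean", "sd"))
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 2))
    abort("`grid_shape` must be three voxel counts >= 2.")
  if (any(spec$voxel_size <= 0)) abort("voxel spacings must be positive.")
  means <- c(spec$head_semi_axes_dist["mean"], spec$neck_radius_dist["mean"],
             spec$neck_length_dist["mean"])
  if (any(means <= 0)) abort("all distribution means must be positive.")
  if (spec$head_semi_axes_dist["mean"] <= spec$neck_radius_dist["mean"])
    abort("mean head semi-axis must exceed mean neck radius.")
  if (spec$n_glomeruli < 0) abort("`n_glomeruli` must be nonnegative.")
  if (spec$vessel_density < 0 || spec$vessel_density >= 1)
    abort("`vessel_density` must be a fraction in [0, 1).")
  if (spec$edge_margin < 0) abort("`edge_margin` must be nonnegative.")
  # capacity check matching the lattice placement: semi-axis draws are
  # truncated at mean + 2 sd, so r bounds the largest possible head
  extent <- (spec$grid_shape - 1) * spec$voxel_size
  r <- spec$head_semi_axes_dist["mean"] + 2 * spec$head_semi_axes_dist["sd"]
  free <- extent - 2 * (spec$edge_margin + r)
  if (spec$n_glomeruli > 0 && any(free < 0))
    abort("grid too small: one head plus edge margin exceeds the stack extent.")
  cap <- prod(floor(free / (2 * r + 2)) + 1)
  if (spec$n_glomeruli > cap)
    abort(sprintf(paste0("grid too small: requested %d glomeruli but at most ",
                         "%d non-overlapping heads fit the stack."),
                  spec$n_glomeruli, cap))
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d glomeruli on %d x %d x %d grid ",
                     "(z,y,x), spacing %.3g/%.3g/%.3g um, seed %d\n"),
              x$n_glomeruli, x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$seed))
  invisible(x)
}

# scale the glomerulus geometry distributions (head semi-axes, neck radius)
# by multiplicative factors; used to build a diseased (enlarged) cohort arm
scale_phantom_spec <- function(spec, head_factor = 1, neck_factor = 1,
                               seed = spec$seed) {
  spec$head_semi_axes_dist <- spec$head_semi_axes_dist * head_factor
  spec$neck_radius_dist <- spec$neck_radius_dist * neck_factor
  spec$seed <- as.integer(seed)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}
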