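#' Detect glomerulus instances in a raw stack
#'
#' The full detection chain on one anisotropic light-sheet stack:
#' z-interpolation to isotropic voxels, global Otsu binarization, geodesic
#' active contour refinement, watershed / ellipsoid-fit instance separation,
#' and exclusion of instances near the stack faces (default margin 5% of
#' each axis extent).
#'
#' @param volume A [volume_stack()].
#' @param margin Edge margin in um (scalar or per-axis `(z, y, x)`);
#'   `NULL` for the 5% default.
#' @param gac_iterations,gac_balloon Active-contour controls, see
#'   [refine_geodesic_active_contour()].
#' @param ... Passed to [separate_instances_ellipse_fit()].
#' @return A [label_map()] on the isotropic grid; attribute `params` records
#'   every effective parameter.
#' @export
segment_glomeruli <- function(volume, margin = NULL, gac_iterations = 50L,
                              gac_balloon = -1, ...) {
  iso <- interpolate_isotropic(volume)
  mask <- binarize_otsu(iso)
  refined <- refine_geodesic_active_contour(iso, mask,
                                            iterations = gac_iterations,
                                            balloon = gac_balloon)
  attr(refined, "voxel_size") <- voxel_size(iso)
  labels <- separate_instances_ellipse_fit(refined, ...)
  if (is.null(margin))
    margin <- 0.05 * (dim(labels) - 1) * voxel_size(labels)
  labels <- exclude_edge_objects(labels, margin)
  attr(labels, "params") <- list(
    otsu_threshold = attr(mask, "threshold"),
    gac_iterations = gac_iterations, gac_balloon = gac_balloon,
    margin_um = margin, extra = list(...))
  labels
}

#' Extract features for labelled instances
#'
#' Meshes each requested instance (marching tetrahedra on its binary field),
#' applies curvature-flow smoothing, and runs the full morphometry chain
#' with an automatic base point (the mesh vertex farthest from the volume
#' centroid, i.e. the distal end of the neck).
#'
#' @param labels A [label_map()].
#' @param ids Instance ids (default: all).
#' @param step_height Stepped-profile height in um; `NULL` for twice the
#'   in-plane voxel size.
#' @param smooth_iterations,smooth_step See [smooth_curvature_flow()].
#' @param ... Passed to [glomerulus_features()].
#' @return A tibble of feature records, one row per instance that could be
#'   measured; failures are recorded in attribute `failures`.
#' @export
features_from_labels <- function(labels, ids = NULL, step_height = NULL,
                                 smooth_iterations = 10L, smooth_step = 0.1,
                                 ...) {
  stopifnot(inherits(labels, "label_map"))
  if (is.null(ids)) ids <- seq_len(n_labels(labels))
  vs <- voxel_size(labels)
  if (is.null(step_height)) step_height <- 2 * min(vs[2:3])
  failures <- character()
  rows <- purrr::map_dfr(ids, function(id) {
    tryCatch({
      mesh <- mesh_from_label(labels, id)
      mesh <- smooth_curvature_flow(mesh, smooth_iterations, smooth_step)
      rec <- glomerulus_features(mesh, base_reference = "auto",
                                 step_height = step_height, id = id, ...)
      tibble::as_tibble(rec)
    }, error = function(e) {
      failures <<- c(failures, sprintf("id %d: %s", id, conditionMessage(e)))
      NULL
    })
  })
  attr(rows, "failures") <- failures
  rows
}

#' One-call analysis of a raw stack
#'
#' [segment_glomeruli()] followed by random instance sampling
#' ([sample_glomeruli()]) and [features_from_labels()].
#'
#' @param volume A [volume_stack()].
#' @param n_sample Instances to sample (default 10 per stack).
#' @param seed Sampling seed.
#' @param margin,... Passed to [segment_glomeruli()] /
#'   [features_from_labels()].
#' @return Feature tibble as from [features_from_labels()].
#' @export
analyze_stack <- function(volume, n_sample = 10L, seed = 1L, margin = NULL,
                          ...) {
  labels <- segment_glomeruli(volume, margin = margin)
  ids <- sample_glomeruli(labels, n = n_sample, seed = seed)
  features_from_labels(labels, ids = ids, ...)
}
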