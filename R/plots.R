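#' Plot a depth-resolved SNR profile
#'
#' @param object A `depth_profile` from [snr_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_um, y = .data$snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Imaging depth (µm)", y = "SNR",
                  title = "Signal-to-noise ratio over imaging depth") +
    ggplot2::theme_minimal()
}

#' Plot a stepped cross-section profile
#'
#' Maximum and minimum caliper widths per step along the base-to-tip axis;
#' gaps (empty steps) are left blank.
#'
#' @param object A `stepped_profile` from [stepped_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stepped_profile <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s_mid, y = .data$diameter,
                                     colour = .data$which)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "Projection along axis (µm)",
                  y = "Caliper width (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

tidyr_pivot <- function(profile) {
  dplyr::bind_rows(
    tibble(s_mid = profile$s_mid, diameter = profile$d_max, which = "max"),
    tibble(s_mid = profile$s_mid, diameter = profile$d_min, which = "min"))
}

#' Plot a cohort experiment
#'
#' Per-feature jittered group values with mean +/- SD bars and the
#' significance stars of the two-group comparisons.
#'
#' @param object A `cohort_experiment` from [run_cohort_experiment()].
#' @param features Features to show (default: the compared ones).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_experiment <- function(object, features = NULL, ...) {
  features <- features %||% names(object$comparisons)
  long <- purrr::map_dfr(features, function(f) {
    tibble(feature = f, group = object$features$group,
           value = object$features[[f]])
  })
  stars <- purrr::map_dfr(object$comparisons[features], function(cmp) {
    tibble(feature = cmp$feature, stars = cmp$stars,
           y = max(object$features[[cmp$feature]], na.rm = TRUE) * 1.06)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun.data = function(v)
      data.frame(y = mean(v), ymin = mean(v) - sd(v), ymax = mean(v) + sd(v)),
      geom = "pointrange", colour = "red3", linewidth = 0.4, size = 0.25) +
    ggplot2::geom_text(data = stars, ggplot2::aes(x = 1.5, y = .data$y,
                                                  label = .data$stars)) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
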