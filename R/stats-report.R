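#' Significance stars
#'
#' The conventional star mapping used in the figures: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Two-group comparison with normality check
#'
#' The two-group workflow used on per-feature tables: each group is first
#' checked for normality with the Shapiro-Wilk test (reported, never used to
#' switch tests automatically), then a two-sample t-test is run and the
#' groups summarized as mean +/- SD. Welch's unequal-variance t-test is the
#' default; set `var_equal = TRUE` for the pooled-variance Student variant.
#'
#' @param values_a,values_b Numeric vectors, each with at least 3 values.
#' @param feature Name of the measured feature (for reporting).
#' @param labels Group labels, length 2.
#' @param var_equal Use the pooled-variance t-test.
#' @return A `group_comparison` object; see [tidy()] and [glance()].
#' @export
compare_two_groups <- function(values_a, values_b, feature = "feature",
                               labels = c("a", "b"), var_equal = FALSE) {
  if (length(values_a) < 3 || length(values_b) < 3)
    abort("each group needs at least 3 values.")
  sw <- function(x) {
    if (sd(x) == 0) return(list(statistic = NA_real_, p.value = NA_real_))
    shapiro.test(x)
  }
  swa <- sw(values_a)
  swb <- sw(values_b)
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  groups <- tibble(
    group = labels,
    n = c(length(values_a), length(values_b)),
    mean = c(mean(values_a), mean(values_b)),
    sd = c(sd(values_a), sd(values_b)),
    shapiro_w = c(unname(swa$statistic), unname(swb$statistic)),
    shapiro_p = c(swa$p.value, swb$p.value))
  structure(list(feature = feature, groups = groups,
                 test = if (var_equal) "Student two-sample t-test"
                        else "Welch two-sample t-test",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stars = p_stars(tt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s\n", x$feature, x$test))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-10s n=%2d  %.4g +/- %.4g\n",
                g$group[i], g$n[i], g$mean[i], g$sd[i]))
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g %s\n",
              x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$groups, feature = x$feature, .before = 1)
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble(feature = x$feature, test = x$test, statistic = x$statistic,
         df = x$df, p_value = x$p_value, stars = x$stars)
}

#' Multi-group comparison (one-way ANOVA + Tukey HSD)
#'
#' For three or more groups: ordinary one-way ANOVA followed by Tukey's
#' multiple-comparison test, with stars on the Tukey-adjusted p-values.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param feature Feature name for reporting.
#' @return A `multi_group_comparison` object; `tidy()` gives the pairwise
#'   table, `glance()` the ANOVA summary.
#' @export
compare_multi_groups <- function(groups, feature = "feature") {
  if (length(groups) < 3) abort("need at least 3 groups (use compare_two_groups otherwise).")
  if (any(lengths(groups) < 3)) abort("each group needs at least 3 values.")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  df <- tibble(value = unlist(groups, use.names = FALSE),
               group = factor(rep(names(groups), lengths(groups)),
                              levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble(comparison = rownames(tk),
                     diff = tk[, "diff"], lwr = tk[, "lwr"],
                     upr = tk[, "upr"], p_adj = tk[, "p adj"],
                     stars = p_stars(tk[, "p adj"]))
  structure(list(feature = feature,
                 groups = dplyr::summarise(
                   dplyr::group_by(df, .data$group),
                   n = dplyr::n(), mean = mean(.data$value),
                   sd = sd(.data$value), .groups = "drop"),
                 f_statistic = an[["F value"]][1],
                 df_between = an[["Df"]][1], df_within = an[["Df"]][2],
                 p_value = an[["Pr(>F)"]][1], pairwise = pairwise),
            class = "multi_group_comparison")
}

#' @export
print.multi_group_comparison <- function(x, ...) {
  cat(sprintf("<multi_group_comparison> %s: one-way ANOVA F(%d, %d) = %.4g, p = %.4g\n",
              x$feature, x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.multi_group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, feature = x$feature, .before = 1)
}

#' @exportS3Method generics::glance
glance.multi_group_comparison <- function(x, ...) {
  tibble(feature = x$feature, f_statistic = x$f_statistic,
         df_between = x$df_between, df_within = x$df_within,
         p_value = x$p_value, stars = p_stars(x$p_value))
}

#' End-to-end synthetic normal-versus-diseased experiment
#'
#' Generates a two-arm phantom cohort ([generate_condition_cohort()]), runs
#' the full detection-to-features pipeline on every volume (or, with
#' `mode = "ground_truth"`, reads the features straight from the analytic
#' ground truth -- useful for fast statistical calibration of the comparison
#' machinery itself), samples up to `n_sample_per_volume` glomeruli per
#' volume, and compares the arms per feature with [compare_two_groups()].
#' Failures in individual volumes are logged and skipped, not fatal.
#'
#' @param normal_spec A [phantom_spec()] for the healthy arm.
#' @param effect Scale factors `c(head = , neck = )`, each >= 1.
#' @param n_per_group Volumes per arm (scalar or length 2).
#' @param n_sample_per_volume Glomeruli analysed per volume (default 10, the
#'   reference workflow's count); scalar or length 2 `(normal, diseased)`.
#' @param seed Master seed; all per-volume seeds derive from it.
#' @param mode `"imaging"` (full pipeline) or `"ground_truth"`.
#' @param features Features to compare.
#' @param ... Passed to [analyze_stack()] in imaging mode.
#' @return A `cohort_experiment` object: `features` (per-glomerulus tibble
#'   with `group`), `comparisons` (list of [compare_two_groups()] results),
#'   `recovery` (measured vs expected group-mean ratios), `failed_volumes`.
#' @export
run_cohort_experiment <- function(normal_spec,
                                  effect = c(head = 1.3, neck = 1.3),
                                  n_per_group = 2L, n_sample_per_volume = 10L,
                                  seed = normal_spec$seed,
                                  mode = c("imaging", "ground_truth"),
                                  features = c("volume_um3", "hmax_um", "nmax_um"),
                                  ...) {
  mode <- match.arg(mode)
  spec <- normal_spec
  spec$seed <- as.integer(seed)
  spec <- structure(spec, class = "phantom_spec")
  cohort <- generate_condition_cohort(spec, effect, n_per_group,
                                      render = mode == "imaging")
  n_sample_per_volume <- rep(as.integer(n_sample_per_volume), length.out = 2)
  failed <- character()
  collect <- function(arm, arm_name, seed_off, n_sample) {
    purrr::imap_dfr(arm, function(ph, i) {
      vol_seed <- derive_seed(seed, 5000 + seed_off + i)
      res <- tryCatch({
        if (mode == "ground_truth") {
          ft <- ph$truth
          if (nrow(ft) == 0) abort("empty ground truth")
          feats <- tibble(id = ft$id, volume_um3 = ft$head_volume_um3,
                          hmax_um = ft$dmax_um, hmin_um = ft$dmin_um,
                          nmax_um = ft$neck_diameter_um,
                          L_um = ft$neck_length_um)
        } else {
          feats <- suppressWarnings(
            analyze_stack(ph$volume, n_sample = n_sample, seed = vol_seed, ...))
        }
        n_take <- min(nrow(feats), n_sample)
        take <- with_seed(vol_seed, sample.int(nrow(feats), n_take))
        dplyr::mutate(feats[take, ], group = arm_name, volume_index = i,
                      .before = 1)
      }, error = function(e) {
        failed <<- c(failed, sprintf("%s volume %d: %s", arm_name, i,
                                     conditionMessage(e)))
        NULL
      })
      res
    })
  }
  all_features <- dplyr::bind_rows(
    collect(cohort$normal, "normal", 0L, n_sample_per_volume[1]),
    collect(cohort$ntn, "ntn", 100L, n_sample_per_volume[2]))
  comparisons <- list()
  for (f in features) {
    va <- all_features[[f]][all_features$group == "normal"]
    vb <- all_features[[f]][all_features$group == "ntn"]
    if (length(va) >= 3 && length(vb) >= 3)
      comparisons[[f]] <- compare_two_groups(va, vb, feature = f,
                                             labels = c("normal", "ntn"))
  }
  expected <- c(volume_um3 = unname(effect["head"])^3,
                hmax_um = unname(effect["head"]),
                hmin_um = unname(effect["head"]),
                nmax_um = unname(effect["neck"]),
                L_um = NA_real_)
  recovery <- purrr::map_dfr(names(comparisons), function(f) {
    g <- comparisons[[f]]$groups
    tibble(feature = f,
           mean_normal = g$mean[g$group == "normal"],
           mean_ntn = g$mean[g$group == "ntn"],
           measured_ratio = g$mean[g$group == "ntn"] / g$mean[g$group == "normal"],
           expected_ratio = unname(expected[f]))
  })
  if (length(failed))
    warn(sprintf("%d volume(s) failed and were skipped.", length(failed)))
  structure(list(features = all_features, comparisons = comparisons,
                 recovery = recovery, failed_volumes = failed,
                 effect = effect, mode = mode),
            class = "cohort_experiment")
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat(sprintf("<cohort_experiment> mode=%s, %d glomeruli (%s)\n", x$mode,
              nrow(x$features),
              paste(sprintf("%s: %d", names(table(x$features$group)),
                            table(x$features$group)), collapse = ", ")))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_experiment <- function(x, ...) {
  purrr::map_dfr(x$comparisons, function(cmp) {
    dplyr::left_join(glance(cmp),
                     x$recovery[x$recovery$feature == cmp$feature, ],
                     by = "feature")
  })
}

#' @exportS3Method generics::glance
glance.cohort_experiment <- function(x, ...) {
  tibble(mode = x$mode, n_normal = sum(x$features$group == "normal"),
         n_ntn = sum(x$features$group == "ntn"),
         n_failed_volumes = length(x$failed_volumes),
         all_significant = all(vapply(x$comparisons, function(z)
           z$p_value < 0.05, logical(1))))
}
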