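#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier curve plot
#'
#' Step curves of estimated survival per group, starting at S(0) = 1,
#' with censoring ticks.
#'
#' @param object A `ctx_km` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctx_km
#' @export
autoplot.ctx_km <- function(object, ...) {
  steps <- object$steps
  origin <- dplyr::distinct(steps, group) %>%
    mutate(time = 0, surv = 1, n_risk = NA_real_, n_event = NA_real_)
  df <- bind_rows(origin, steps) %>% arrange(group, time)
  cens <- steps %>% filter(n_event == 0)
  ggplot2::ggplot(df, ggplot2::aes(time, surv, colour = group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.8,
                        show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot the cells of a simulated or imported field
#'
#' Cell positions coloured by phenotype (tumor cells grey), with the
#' image-convention y axis (origin top-left, y increasing downward).
#'
#' @param field A phenotyped [field_tbl()].
#' @return A ggplot object.
#' @export
plot_field <- function(field) {
  lab <- vapply(field$phenotypes, function(p) {
    if (length(p) == 0L) "other" else p[length(p)]
  }, character(1))
  df <- tibble(x_um = field$x_um, y_um = field$y_um, phenotype = lab)
  ggplot2::ggplot(df, ggplot2::aes(x_um, y_um, colour = phenotype)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_classic()
}

#' Group-comparison box plot for one per-patient metric
#'
#' Floating boxes (25th-75th percentile, whiskers to the extremes)
#' with jittered patient points, the display convention of
#' immune-contexture group comparisons.
#'
#' @param metrics Long per-patient metric table (columns `patient_id`,
#'   `metric`, `value`) as produced by [run_pipeline()].
#' @param metric_name Metric to plot.
#' @param groups Data frame with `patient_id` and the grouping column.
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_metric_by_group <- function(metrics, metric_name, groups, group) {
  df <- metrics %>%
    filter(metric == metric_name) %>%
    left_join(groups, by = "patient_id")
  df$.group <- df[[group]]
  ggplot2::ggplot(df, ggplot2::aes(.data$.group, value)) +
    ggplot2::geom_boxplot(coef = Inf, width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, size = 1.5, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = metric_name) +
    ggplot2::theme_classic()
}
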