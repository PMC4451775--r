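#' Forest plot of a pooled result
#'
#' Per-study odds ratios with 95% confidence intervals (point size
#' proportional to pooling weight), a dashed line at OR = 1 and a solid
#' line at the pooled estimate, on a log x-axis.
#'
#' @param pooled A `meta_pooled` object.
#' @return A ggplot object.
#' @export
plot_forest <- function(pooled) {
  stopifnot(inherits(pooled, "meta_pooled"))
  d <- tidy(pooled)
  label_cols <- intersect(c("study_id", "disease", "snp"), names(d))
  d$label <- if (length(label_cols) > 0) {
    do.call(paste, c(d[label_cols], sep = " / "))
  } else {
    paste("study", seq_len(nrow(d)))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = stats::reorder(.data$label, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = pooled$or, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct), shape = 15) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "odds ratio (log scale)", y = NULL,
      title = sprintf("%s-effects pooled OR %.3f (%.3f-%.3f), k = %d",
                      pooled$model_effects, pooled$or, pooled$ci_low,
                      pooled$ci_high, pooled$k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meta_pooled <- function(object, ...) plot_forest(object)

#' Funnel plot
#'
#' Study log odds ratios against their standard errors (inverted y-axis,
#' the meta-analysis convention), with the pooled estimate and the pseudo
#' 95% limits. Asymmetry of the scatter suggests small-study effects such
#' as publication bias.
#'
#' @param fd A `funnel_data` object from [funnel_data()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(fd) {
  stopifnot(inherits(fd, "funnel_data"))
  ggplot2::ggplot(fd$points, ggplot2::aes(x = .data$log_or, y = .data$se)) +
    ggplot2::geom_line(data = fd$limits,
                       ggplot2::aes(x = .data$lower, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_line(data = fd$limits,
                       ggplot2::aes(x = .data$upper, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_vline(xintercept = fd$pooled_log_or, colour = "steelblue") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "standard error") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.funnel_data <- function(object, ...) plot_funnel(object)
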