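# ggplot2 helpers for the main result types.

#' Coefficient plot for a cascade regression fit
#'
#' Dot-and-whisker plot of the coefficients with their (cluster-robust
#' where available) confidence intervals; the intercept is omitted by
#' default.
#'
#' @param object A `cascade_fit`.
#' @param se,conf_level Passed to [tidy.cascade_fit()].
#' @param intercept Include the intercept row? (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cascade_fit
#' @export
autoplot.cascade_fit <- function(object, se = "cluster", conf_level = 0.95,
                                 intercept = FALSE, ...) {
  td <- tidy(object, se = se, conf_level = conf_level)
  if (!intercept) td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient", y = NULL,
                  title = paste0(object$dv, " (", object$family, ", size >= ",
                                 object$min_size, ")")) +
    ggplot2::theme_minimal()
}

#' Bias and coverage plot for a recovery report
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object showing per-term estimate distributions against
#'   the true values.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  est <- as_tibble(object$estimates) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "estimate")
  truth <- object$summary[c("term", "true")]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(data = truth, ggplot2::aes(y = .data$true),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "Recovered emotion coefficients (x = truth)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dominant-emotion frequency bar chart
#'
#' @param features A `cascade_features` tibble.
#' @param group_by Grouping column (default `"event_label"`).
#' @return A ggplot object.
#' @export
plot_emotion_frequency <- function(features, group_by = "event_label") {
  tab <- emotion_frequency_table(features, group_by = group_by)
  long <- tidyr::pivot_longer(tab, -"emotion", names_to = "group",
                              values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$emotion, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of cascades", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Cascade size distribution on log-log axes
#'
#' The complementary cumulative share of cascades at or above each size,
#' the standard view of a right-skewed reshare size distribution.
#'
#' @param features A `cascade_features` tibble (or anything with `size`).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(features) {
  sz <- sort(unique(features$size))
  ccdf <- vapply(sz, function(s) mean(features$size >= s), numeric(1))
  df <- tibble(size = sz, ccdf = ccdf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$ccdf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cascade size", y = "P(size >= s)") +
    ggplot2::theme_minimal()
}
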