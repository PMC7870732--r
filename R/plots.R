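#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of methods (kg)", y = "Difference, method - reference (kg)",
      title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f] kg",
                      object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.contingency3 <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col_class, y = .data$row_class,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = attr(object, "col_method"),
                  y = attr(object, "row_method")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Scatter of paired percent changes around the response threshold
#'
#' Plots each patient's percent change in SUL peak under the two LBM
#' algorithms with the +/- threshold lines; discordant classifications are
#' highlighted. Visualises why discordance concentrates near the threshold.
#'
#' @param results classified cohort (e.g. [classify_percist_cohort()] or
#'   [percist_compare()] output) with `percent_change_pe`,
#'   `percent_change_lc` and `discordant` columns.
#' @param threshold_pct decision threshold drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_threshold_bands <- function(results, threshold_pct = 30) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$percent_change_pe,
                               y = .data$percent_change_lc,
                               colour = .data$discordant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * threshold_pct,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * threshold_pct,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = "Discordant"
    ) +
    ggplot2::labs(x = "Percent change, PE-based SUL peak (%)",
                  y = "Percent change, LC-based SUL peak (%)") +
    ggplot2::theme_minimal()
}
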