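#' Q-Q plot of association P values
#'
#' @param qq Output of [qq_table()].
#' @return A ggplot: observed versus expected `-log10(P)` with the identity
#'   line.
#' @export
plot_qq <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(P))),
                  y = expression(Observed ~ -log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' Polygenic-score performance across P-value thresholds
#'
#' @param scan Output of [threshold_scan()].
#' @param metric Column to plot (default liability-scale R2).
#' @return A ggplot of the metric against the (log-scaled) threshold grid.
#' @export
plot_threshold_scan <- function(scan, metric = "r2_liability") {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$threshold,
                                     y = .data[[metric]])) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "P-value threshold", y = metric) +
    ggplot2::theme_minimal()
}

#' Group polygenic-score profile with confidence intervals
#'
#' @param profile Output of [group_profile()].
#' @return A ggplot of the covariate-adjusted standardized group means with
#'   95% CIs.
#' @export
plot_group_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::labs(x = NULL, y = "standardized PRS mean (95% CI)") +
    ggplot2::theme_minimal()
}
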