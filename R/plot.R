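#' Plot a feature's group curves and significant intervals
#'
#' Draws the two fitted group curves with pointwise ~95% bands
#' (eta_hat +- 1.96 SE) over the time grid and shades the intervals
#' called significant, giving the standard one-panel summary of a
#' time-interval differential analysis. Requires ggplot2.
#'
#' @param result a `feature_result` from [analyze_feature()].
#' @return a ggplot object.
#' @importFrom rlang .data
#' @export
plot_feature_result <- function(result) {
  if (!inherits(result, "feature_result"))
    abort_argument("`result` must come from analyze_feature().")
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_argument("plot_feature_result() requires the ggplot2 package.")
  grid <- result$fit_group1$grid
  curves <- rbind(
    data.frame(time = grid$points, group = result$fit_group1$group,
               eta = result$fit_group1$eta_hat, se = result$fit_group1$se),
    data.frame(time = grid$points, group = result$fit_group2$group,
               eta = result$fit_group2$eta_hat, se = result$fit_group2$se))
  sig <- result$intervals[result$intervals$significant, ]
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time))
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(sig),
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey85")
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eta - 1.96 * .data$se,
                                      ymax = .data$eta + 1.96 * .data$se,
                                      fill = .data$group), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eta, colour = .data$group),
                       linewidth = 0.8) +
    ggplot2::labs(x = "time", y = "adjusted level",
                  title = result$feature_id,
                  subtitle = sprintf("%d of %d intervals significant at alpha = %g",
                                     nrow(sig), nrow(result$intervals),
                                     result$alpha)) +
    ggplot2::theme_minimal()
}
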