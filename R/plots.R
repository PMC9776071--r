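#' Violin-style plot of ROI descriptor distributions across cases
#'
#' @param values Named list of numeric vectors (one per case), e.g. the
#'   `values` element of [roi_stats()] results.
#' @param ylab Axis label (quantity and units).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_roi_distribution <- function(values, ylab = "TAWSS (Pa)") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_roi_distribution requires ggplot2")
  df <- data.frame(
    case = rep(names(values), lengths(values)),
    value = unlist(values, use.names = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "black") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
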