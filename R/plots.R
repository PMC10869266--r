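#' @export
autoplot.profile_trace <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position_mm, y = .data$a254)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Position (mm from gradient top)", y = "A254 (a.u.)",
      title = sprintf("%s | %s | t = %g min", trace_sample_id(object),
                      trace_treatment(object), trace_runoff_time(object))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    bounds <- c(regions$monosome_region[1], regions$polysome_region[1])
    p <- p + ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @export
autoplot.runoff_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Runoff time (min)",
                  y = "Fold change vs CHX control",
                  title = series_kind(object)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble(time_min = seq(0, max(object$data$time_min), length.out = 200))
  grid$value <- predict(object, grid$time_min)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Runoff time (min)", y = "Fold change vs CHX control",
      title = sprintf("%s: k = %.3g /min, plateau = %.3g, R² = %.3f",
                      object$kind, object$k, object$plateau, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated-test result
#'
#' @param diff An [apply_rejections()] result.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff) {
  if (is.null(diff$significant)) diff$significant <- FALSE
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$adj_p),
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = paste(attr(diff, "contrast"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}
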