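# ggplot2 displays for runs and scenarios.

#' Plot a pipeline run
#'
#' Two stacked panels: the raw, smoothed and corrected signal with
#' registered anomaly groups shaded, and the DRA-transformed signal with
#' the threshold band.
#'
#' @param object An `anomaly_run`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @export
autoplot.anomaly_run <- function(object, ...) {
  d <- object$data
  long <- tidyr::pivot_longer(
    d[, c("time_min", "raw", "smoothed", "corrected")],
    cols = c("raw", "smoothed", "corrected"),
    names_to = "signal", values_to = "pF_cm")
  long$signal <- factor(long$signal, levels = c("raw", "smoothed", "corrected"))
  p1 <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$time_min, y = .data$pF_cm,
                                     color = .data$signal))
  if (nrow(object$anomalies)) {
    p1 <- p1 + ggplot2::geom_rect(
      data = object$anomalies,
      ggplot2::aes(xmin = .data$start_min, xmax = .data$end_min),
      ymin = -Inf, ymax = Inf, fill = "orange", alpha = 0.25,
      inherit.aes = FALSE)
  }
  p1 <- p1 + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(y = "permittivity (pF/cm)", x = NULL, color = NULL) +
    ggplot2::theme_minimal()

  p2 <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min,
                                        y = .data$perm_d)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold_upper),
                       linetype = "dashed", color = "red", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold_lower),
                       linetype = "dashed", color = "red", na.rm = TRUE) +
    ggplot2::labs(y = "transformed signal (pF/cm)", x = "time (min)") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(2, 1))
}

#' Plot a synthetic scenario
#'
#' Clean and noisy traces with the injected-anomaly annotations shaded.
#'
#' @param object A `perm_scenario`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_scenario <- function(object, ...) {
  d <- object$signal
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min))
  if (nrow(object$annotations)) {
    p <- p + ggplot2::geom_rect(
      data = object$annotations,
      ggplot2::aes(xmin = .data$start_min, xmax = .data$end_min),
      ymin = -Inf, ymax = Inf, fill = "orange", alpha = 0.25,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$permittivity_pF_cm),
                       color = "steelblue", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$clean_pF_cm),
                       color = "black", linewidth = 0.4) +
    ggplot2::labs(x = "time (min)", y = "permittivity (pF/cm)") +
    ggplot2::theme_minimal()
}
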