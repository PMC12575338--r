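#' @export
autoplot.sysobs_driver <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "scene_boundaries"),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = "driver (a.u.)",
                  title = "Exogenous driver") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sysobs_observed <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("h_mu", "h_M"),
                              names_to = "channel", values_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$signal,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(h_mu = "black", h_M = "firebrick"),
      labels = c(h_mu = "micro", h_M = "macro")
    ) +
    ggplot2::labs(x = "time (s)", y = "signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sysobs_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$free_energy)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p = %.3g", .data$probability)
    ), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "free energy (relative, nats)",
                  title = "Reduced-model comparison") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sysobs_validation <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$noise_mode,
                               y = .data$evidence_gap)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "process-noise mode",
                  y = "evidence gap (correct - incorrect, nats)") +
    ggplot2::theme_minimal()
}

#' Plot an observed pair with its driver
#'
#' @param observed A `sysobs_observed`.
#' @param driver Optional `sysobs_driver` plotted beneath the channels.
#' @return A ggplot object.
#' @export
plot_pair <- function(observed, driver = NULL) {
  p <- autoplot(observed)
  if (!is.null(driver)) {
    drv <- tibble::as_tibble(driver)
    p <- p + ggplot2::geom_line(
      data = drv,
      ggplot2::aes(x = .data$time, y = .data$value),
      inherit.aes = FALSE, colour = "steelblue", alpha = 0.4
    )
  }
  p
}
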