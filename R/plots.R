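# ggplot2 visualisations for traces and equivalence results.

#' Plot a reconstructed (or truth) trace with protocol segments
#'
#' HbT change and StO2 over time, with the breath-hold and deep-breathing
#' segments shaded.
#'
#' @param trace Data frame with `time_s` and at least one of `d_hbt_uM` /
#'   `hbt_uM` and `sto2_pct`.
#' @param protocol A [breathing_protocol()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, protocol = breathing_protocol()) {
  hbt_col <- if ("d_hbt_uM" %in% names(trace)) "d_hbt_uM" else "hbt_uM"
  long <- tibble(
    time_s = rep(trace$time_s, 2),
    value = c(trace[[hbt_col]], trace$sto2_pct),
    signal = rep(c(
      if (hbt_col == "d_hbt_uM") "HbT change [uM]" else "HbT [uM]",
      "StO2 [%]"
    ), each = nrow(trace))
  )
  shade <- protocol[protocol$label %in% c("breath_hold", "deep_breathing"), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.15
    ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(breath_hold = "#d95f02", deep_breathing = "#1b9e77"),
      name = "segment"
    ) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of an equivalence battery
#'
#' Median-of-differences with 95% CI per artery pair, faceted by parameter,
#' against the `+/-` equivalence bounds.
#'
#' @param object A [equivalence_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_equivalence <- function(object, ...) {
  eq <- object$equivalence
  if (nrow(eq) == 0) stop("no comparisons to plot", call. = FALSE)
  bounds <- dplyr::distinct(eq, .data$parameter, .data$delta)
  ggplot2::ggplot(eq, ggplot2::aes(x = .data$mod, y = .data$pair)) +
    ggplot2::geom_rect(
      data = bounds, inherit.aes = FALSE,
      ggplot2::aes(xmin = -.data$delta, xmax = .data$delta,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$equivalent), size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "#d95f02")) +
    ggplot2::labs(x = "median of differences [95% CI]", y = NULL) +
    ggplot2::theme_minimal()
}
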