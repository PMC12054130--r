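#' Render a cover-test trajectory figure
#'
#' Plots both eyes' horizontal gaze against time with an occlusion
#' indicator bar along the top (flat while viewing, raised while
#' occluded), the fitted logistic curve overlaid on the covered-eye
#' channel, a vertical dotted line at the stabilization time, and
#' annotations for the deviation angle `a` and the maximum deviation
#' `d`. The stabilization line is omitted (with a warning) when it
#' falls outside the plotted window.
#'
#' @param trace a [gaze_trace()].
#' @param fit the [fit_logistic()] result for the trace.
#' @param metrics the [trace_metrics()] result for the trace.
#' @param path output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
render_trace_figure <- function(trace, fit, metrics, path) {
  stopifnot(inherits(trace, "gaze_trace"), inherits(fit, "logistic_fit"))
  df <- data.frame(
    time_s = rep(trace$time_s, 2L),
    gaze_deg = c(trace$fixating_deg, trace$covered_deg),
    eye = rep(c("fixating eye", "covered eye"), each = length(trace$time_s)))
  df <- df[!is.na(df$gaze_deg), ]

  # fitted deviation mapped back to covered-eye coordinates
  tt <- trace$time_s
  f_dev <- predict_logistic(fit, tt)
  sgn <- if (trace$covered_eye_side == "left") 1 else -1
  fit_df <- data.frame(time_s = tt, gaze_deg = sgn * f_dev)

  rng <- range(df$gaze_deg, fit_df$gaze_deg, na.rm = TRUE)
  bar_lo <- rng[2] + 0.06 * diff(rng) + 0.2
  bar_hi <- bar_lo + 0.08 * diff(rng) + 0.2
  occ_df <- data.frame(time_s = tt,
                       y = ifelse(tt >= 0, bar_hi, bar_lo))

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$gaze_deg)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$eye), linewidth = 0.4) +
    ggplot2::geom_line(data = fit_df, colour = "black", linewidth = 0.8) +
    ggplot2::geom_step(data = occ_df, ggplot2::aes(y = .data$y),
                       colour = "grey30", linewidth = 0.6) +
    ggplot2::labs(x = "time from occlusion onset (s)",
                  y = "horizontal gaze (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()

  t_star <- metrics$stabilization_time_s
  if (is.finite(t_star) && t_star >= min(tt) && t_star <= max(tt)) {
    p <- p + ggplot2::geom_vline(xintercept = t_star, linetype = "dotted")
  } else {
    warning("stabilization time outside the plotted window; line omitted",
            call. = FALSE)
  }
  lab <- sprintf("a = %.2f deg, d = %.2f deg", metrics$angle_deg,
                 metrics$max_deviation_deg)
  p <- p + ggplot2::annotate("text", x = min(tt), y = rng[1],
                             label = lab, hjust = 0, vjust = 0, size = 3)
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 120)
  invisible(path)
}
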