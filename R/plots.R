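# ggplot2 visualisations for the main result types.

#' Plot a filter fit
#'
#' Measured stream, filtered observable displacement (`Xr + C`) and the
#' maximum-horizon prediction over time.
#'
#' @param object A [run_filter()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.resp_kf <- function(object, ...) {
  tr <- object$trace
  df <- tidyr::pivot_longer(
    dplyr::transmute(
      tr,
      time_s = .data$time_s,
      measured = .data$z_mm,
      filtered = .data$xr_mm + .data$c_mm,
      predicted = .data$pred_mm
    ),
    -"time_s", names_to = "series", values_to = "mm"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mm, colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time [s]", y = "displacement [mm]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot gating events over the measured signal
#'
#' @param object A [run_gating()] result.
#' @param signal Optional [resp_signal()] drawn underneath the event markers.
#' @param gold Optional gold peak times \[s\] drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.resp_gating <- function(object, signal = NULL, gold = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(signal)) {
    p <- p + ggplot2::geom_line(
      data = signal,
      ggplot2::aes(.data$time_s, .data$displacement_mm),
      colour = "grey50"
    )
  }
  if (!is.null(gold)) {
    p <- p + ggplot2::geom_vline(xintercept = gold, linetype = "dashed",
                                 colour = "goldenrod3")
  }
  p +
    ggplot2::geom_vline(
      data = tibble::as_tibble(object),
      ggplot2::aes(xintercept = .data$t_prompt_s),
      colour = "#c0392b"
    ) +
    ggplot2::labs(x = "time [s]", y = "displacement [mm]",
                  title = sprintf("gating prompts (mode %s)", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot the target-point error comparison of an evaluation
#'
#' @param object A [compare_modes()] result.
#' @param ... Unused.
#' @return A ggplot of TPE(t) per mode.
#' @exportS3Method ggplot2::autoplot
autoplot.resp_eval <- function(object, ...) {
  ggplot2::ggplot(object$tpe,
                  ggplot2::aes(.data$time_s, .data$tpe_mm, colour = .data$mode)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time [s]", y = "target point error [mm]", colour = "mode") +
    ggplot2::theme_minimal()
}

#' Feature-space plot of breathing classification
#'
#' Scatter of the amplitude and phase irregularity indices, point size by
#' mean amplitude, coloured by label when present.
#'
#' @param features Tibble from [breath_features()] or [classify_breathing()].
#' @return A ggplot.
#' @export
plot_breath_features <- function(features) {
  p <- ggplot2::ggplot(
    features,
    ggplot2::aes(.data$Ia_mm, .data$Ip_s, size = .data$Ma_mm)
  )
  if ("label" %in% names(features)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::labs(x = "amplitude irregularity Ia [mm]",
                  y = "phase irregularity Ip [s]", size = "Ma [mm]") +
    ggplot2::theme_minimal()
}
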