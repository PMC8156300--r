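#' Plot an ICP curve with its markers and reference envelopes
#'
#' Renders the survival-style ICP curve (percentage of the recording at or
#' above each phase angle) with the median (`*`), 25th (`o`) and 75th (`x`)
#' percentile markers, optionally over shaded normal/abnormal cohort
#' envelopes.
#'
#' @param object A `taa_icp` curve.
#' @param envelope Optional envelope table from [build_envelopes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.taa_icp <- function(object, envelope = NULL, ...) {
  dat <- icp_plot_data(object, envelope)
  curve <- dplyr::filter(dat, .data$part == "curve")
  markers <- dplyr::filter(dat, .data$part == "marker")
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$theta_deg, y = .data$icp_pct))
  if (!is.null(envelope)) {
    p <- p +
      ggplot2::geom_ribbon(
        data = envelope,
        ggplot2::aes(x = .data$theta_deg, ymin = .data$normal_lo,
                     ymax = .data$normal_hi),
        inherit.aes = FALSE, fill = "darkgreen", alpha = 0.25
      ) +
      ggplot2::geom_ribbon(
        data = envelope,
        ggplot2::aes(x = .data$theta_deg, ymin = .data$abnormal_lo,
                     ymax = .data$abnormal_hi),
        inherit.aes = FALSE, fill = "orange", alpha = 0.25
      )
  }
  p +
    ggplot2::geom_step(linewidth = 0.8, colour = "purple4") +
    ggplot2::geom_point(
      data = markers,
      ggplot2::aes(shape = .data$marker), size = 3, stroke = 1.2
    ) +
    ggplot2::scale_shape_manual(
      values = c(median = 8, q25 = 1, q75 = 4), name = "marker"
    ) +
    ggplot2::labs(
      x = "Phase difference (degrees)",
      y = "Time at or above angle (%)",
      title = "Inverse cumulative percentage of phase"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 180), ylim = c(0, 100))
}

#' Plot a Konno–Mead loop
#'
#' Abdominal against rib-cage excursion; a closed line means synchronous
#' motion, an open loop asynchrony, a negative slope paradoxical breathing.
#'
#' @param object A `taa_km` loop from [konno_mead()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.taa_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rc, y = .data$abd)) +
    ggplot2::geom_path(alpha = 0.6, colour = "steelblue4") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Rib cage (centered, a.u.)",
                  y = "Abdomen (centered, a.u.)",
                  title = "Konno–Mead loop")
}

#' Plot the cross-validation curve of a fitted classifier
#'
#' Misclassification error against log(lambda) with one-SE error bars, the
#' selected lambda marked by a dashed line, and the number of nonzero
#' coefficients annotated along the top.
#'
#' @param object A `taa_enet` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.taa_enet <- function(object, ...) {
  cv <- object$cv_curve
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data$error_mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$error_mean - .data$error_se,
                   ymax = .data$error_mean + .data$error_se),
      width = 0.05, colour = "grey60"
    ) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = log(object$lambda_selected),
                        linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(y = max(.data$error_mean + .data$error_se),
                                    label = .data$nzero),
                       vjust = -0.8, size = 2.6, colour = "grey40") +
    ggplot2::labs(x = "log(lambda)", y = "CV misclassification error",
                  title = "Elastic-net cross-validation curve")
}
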