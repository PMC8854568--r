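# ggplot2 displays for the main result types.

#' Plot mean PAI trajectories of a panel
#'
#' Survey-mean PAI (or relative PAI when present) by time, coloured by edge
#' class and facetted by stratum.
#'
#' @param object PAI panel tibble.
#' @param relative Plot `pai_rel` (percent of baseline) if available.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pai_panel <- function(object, relative = "pai_rel" %in% names(object),
                               ...) {
  plot_pai_trajectories(object, relative = relative)
}

#' @rdname autoplot.pai_panel
#' @param panel PAI panel tibble.
#' @export
plot_pai_trajectories <- function(panel, relative = "pai_rel" %in% names(panel)) {
  value <- if (relative) "pai_rel" else "pai"
  df <- panel |>
    dplyr::group_by(.data$survey_time, .data$edge_class, .data$stratum) |>
    dplyr::summarise(y = mean(.data[[value]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$survey_time, .data$y,
                                   colour = .data$edge_class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = NULL, colour = "edge class",
                  y = if (relative) "PAI (% of baseline)"
                      else expression(PAI ~ (m^2 ~ m^-2))) +
    ggplot2::theme_minimal()
}

#' Plot a vertical PAD change profile
#'
#' @param object A [pad_change_profile()] tibble.
#' @param boundary Optional [detect_strata_boundary()] result to mark.
#' @param ... Unused.
#' @return A ggplot (height on the y axis).
#' @export
autoplot.change_profile <- function(object, boundary = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$delta_pad, .data$height)) +
    ggplot2::geom_path() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(Delta * PAD ~ (m^2 ~ m^-3)),
                  y = "height above ground (m)") +
    ggplot2::theme_minimal()
  if (!is.null(boundary) && !is.na(boundary$boundary))
    p <- p + ggplot2::geom_hline(yintercept = boundary$boundary,
                                 colour = "red", linetype = 3)
  p
}

#' Plot the edge gradient and its fitted asymptotic curve
#'
#' @param panel PAI panel rows used for the fit.
#' @param fit Optional [fit_edge_model()] result; its curve is overlaid.
#' @param hockey Optional [fit_hockey_stick()] result; breakpoint marked.
#' @return A ggplot.
#' @export
plot_edge_gradient <- function(panel, fit = NULL, hockey = NULL) {
  p <- ggplot2::ggplot(panel, ggplot2::aes(.data$distance_to_edge,
                                           .data$pai)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::labs(x = "distance to edge (m)",
                  y = expression(PAI ~ (m^2 ~ m^-2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    b <- fit$beta
    p <- p + ggplot2::geom_function(
      fun = function(x) b[1] + b[2] * exp(-b[3] * x), colour = "red")
  }
  if (!is.null(hockey) && hockey$supported)
    p <- p + ggplot2::geom_vline(xintercept = hockey$breakpoint,
                                 linetype = 3, colour = "blue")
  p
}

#' Plot predicted trajectories with their permutation envelope
#'
#' @param object A [permutation_ci()] result.
#' @param ... Unused.
#' @return A ggplot of predicted cell means with ribbons.
#' @export
autoplot.permutation_envelope <- function(object, ...) {
  df <- object$cell_envelope
  df$t <- as.integer(df$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$pai,
                                   colour = .data$edge_class,
                                   fill = .data$edge_class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "survey", y = expression(PAI ~ (m^2 ~ m^-2)),
                  colour = "edge class", fill = "edge class") +
    ggplot2::theme_minimal()
}

#' Plot running rainfall and the classified dry season
#'
#' @param object A [classify_dry_season()] result.
#' @param ... Unused.
#' @return A ggplot with the threshold line and shaded dry spells.
#' @export
autoplot.season_labels <- function(object, ...) {
  s <- object$series
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$date, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL,
                  y = sprintf("%d-day rainfall (mm)", object$window)) +
    ggplot2::theme_minimal()
  if (nrow(object$windows) > 0)
    p <- p + ggplot2::geom_rect(
      data = object$windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf), alpha = 0.15)
  p
}
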