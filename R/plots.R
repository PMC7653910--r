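#' Plot a trajectory
#'
#' @param object An `epi_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the compartment fractions against time.
#' @method autoplot epi_trajectory
#' @export
autoplot.epi_trajectory <- function(object, ...) {
  tidy.epi_trajectory(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$fraction,
                                 colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "population fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay an ensemble of (rescaled) infectious curves
#'
#' Reproduces the curve-collapse picture: one line per trajectory. Pass raw
#' trajectories for the absolute-time fan and [rescale_time()]d ones for the
#' collapsed bundle.
#'
#' @param trajs A list of `epi_trajectory` objects.
#' @param compartment Which compartment to draw.
#' @param scaled Logical, only affects the x-axis label.
#' @return A ggplot.
#' @export
plot_collapse <- function(trajs, compartment = "i", scaled = TRUE) {
  compartment <- arg_match(compartment, c("s", "e", "i", "r"))
  df <- purrr::imap(trajs, function(tr, k) {
    tibble(member = k, time = tr$time, value = tr[[compartment]])
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$member)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::labs(
      x = if (scaled) "scaled time (alpha * gamma * t)" else "time (days)",
      y = paste0("fraction (", compartment, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the scaled peak time against the basic reproduction number
#'
#' @param object A `peak_curve` from [peak_scaling_curve()].
#' @param ... Unused.
#' @return A ggplot of mean `alpha * gamma * delta_t` versus `r0` with a
#'   +/- 1 sd ribbon.
#' @method autoplot peak_curve
#' @export
autoplot.peak_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r0, y = .data$mean_scaled)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_scaled - .data$sd_scaled,
                                      ymax = .data$mean_scaled + .data$sd_scaled),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "basic reproduction number",
                  y = "scaled peak time (alpha * gamma * dt)") +
    ggplot2::theme_minimal()
}
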