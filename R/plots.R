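#' Plot the capture-time curve
#'
#' Log-log plot of the scaled mean capture time versus polymerization index,
#' with the large-N `N^(3/2)` power law overlaid for reference.
#'
#' @param curve A tibble from [capture_time()] (columns `N`, `tau_scaled`).
#' @param show_power_law Overlay a line of slope 3/2 anchored at the last
#'   point. Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_capture_time <- function(curve, show_power_law = TRUE) {
  stopifnot(all(c("N", "tau_scaled") %in% names(curve)))
  pos <- dplyr::filter(curve, .data$tau_scaled > 0)
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$N, .data$tau_scaled)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "polymerization index N",
                  y = expression(tau / tau[0]),
                  title = "Mean time to capture of the tethered ligand") +
    ggplot2::theme_minimal()
  if (show_power_law && nrow(pos) > 1) {
    anchor <- pos[nrow(pos), ]
    p <- p + ggplot2::geom_abline(
      slope = 1.5,
      intercept = log10(anchor$tau_scaled) - 1.5 * log10(anchor$N),
      linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' Plot a steady-state concentration profile
#'
#' @param profile A tibble from [concentration_profile()].
#' @return A ggplot object showing `c(x)` between the capture and
#'   reflecting spheres.
#' @export
plot_concentration_profile <- function(profile) {
  stopifnot(all(c("x", "c") %in% names(profile)))
  ggplot2::ggplot(profile, ggplot2::aes(.data$x, .data$c)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = expression(x == r / r[0]),
                  y = "steady-state concentration c(x)",
                  title = "Concentration between capture and reflecting spheres") +
    ggplot2::theme_minimal()
}

#' Autoplot a dose-response fit
#'
#' Data points, the fitted curve, and (dashed) the curve at the reference
#' parameters.
#'
#' @param object A [fit_dose_response()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(N = exp(seq(log(min(d$N)), log(max(d$N)),
                                     length.out = 200)))
  grid$dM <- dm_theory(grid$N, object$params["beta"],
                       object$params["gamma"])
  ggplot2::ggplot(d, ggplot2::aes(.data$N, .data$dM)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "polymerization index N",
                  y = expression(Delta * M ~ "(%)"),
                  title = "Tether-length dose-response fit") +
    ggplot2::theme_minimal()
}
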