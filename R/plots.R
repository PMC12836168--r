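# ggplot2 display methods. All plots are headless-safe (no device opened).

#' @describeIn autoplot_chemotaxgel Intensity versus distance, one line per
#'   time point.
#' @export
autoplot.diffusion_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x_um, y = .data$intensity,
                 color = factor(.data$t_s / 60),
                 group = factor(.data$t_s))) +
    geom_line() +
    labs(
      x = "distance from well rim (µm)",
      y = if (is_normalized(object)) "normalized intensity" else "intensity (a.u.)",
      color = "time (min)"
    ) +
    theme_minimal()
}

#' @describeIn autoplot_chemotaxgel Data and fitted point-source curves.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- object$data
  ggplot(df, aes(x = .data$x_um, color = factor(.data$t_s / 60))) +
    geom_point(aes(y = .data$intensity), size = 0.8, alpha = 0.6) +
    geom_line(aes(y = .data$fitted)) +
    labs(
      x = "distance from well rim (µm)", y = "intensity",
      color = "time (min)",
      title = sprintf("D = %.4g µm²/s", object$D_hat)
    ) +
    theme_minimal()
}

#' @describeIn autoplot_chemotaxgel Per-quadrant migrated area fraction
#'   over time.
#' @export
autoplot.migration_result <- function(object, ...) {
  df <- object$series |>
    tidyr::pivot_longer(c("nw", "ne", "sw", "se"),
                        names_to = "quadrant", values_to = "area_fraction") |>
    mutate(quadrant = toupper(.data$quadrant))
  ggplot(df, aes(x = .data$time_s / 3600, y = .data$area_fraction,
                 color = .data$quadrant)) +
    geom_line() +
    labs(x = "time (h)", y = "migrated area fraction",
         title = sprintf("well %s (%s)", object$well, object$condition)) +
    theme_minimal()
}

#' Plot methods for chemotaxgel result objects
#'
#' `ggplot2::autoplot()` methods are provided for [diffusion_profile()],
#' [fit_diffusion_coefficient()] fits and [migration_time_series()]
#' results; [plot_spider_chart()] draws the terminal quadrant areas as a
#' closed radar polygon per condition.
#'
#' @param object The result object to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_chemotaxgel
NULL

#' Spider (radar) chart of terminal quadrant areas
#'
#' @param spider A [spider_chart_export()] tibble.
#' @return A ggplot object (polar coordinates, one polygon per condition
#'   and well).
#' @export
plot_spider_chart <- function(spider) {
  quads <- c("NW", "NE", "SE", "SW")  # circular order
  df <- spider |>
    mutate(quadrant = factor(.data$quadrant, levels = quads),
           group = paste(.data$condition, .data$well))
  closed <- bind_rows(df, df |> filter(.data$quadrant == quads[1]))
  ggplot(closed, aes(x = .data$quadrant, y = .data$area_fraction,
                     group = .data$group, color = .data$condition)) +
    geom_polygon(fill = NA) +
    geom_point() +
    coord_polar() +
    labs(x = NULL, y = "terminal migrated area fraction") +
    theme_minimal()
}

#' Frequency sweep with the 1 Hz reporting point
#'
#' @param sweep A [frequency_sweep()] (replicates overlaid).
#' @param frequency_hz Reporting frequency to mark (default 1).
#' @return A ggplot object on log-log axes.
#' @export
plot_frequency_sweep <- function(sweep, frequency_hz = 1) {
  df <- as_tibble(sweep) |>
    tidyr::pivot_longer(c("g_prime_pa", "g_double_prime_pa"),
                        names_to = "modulus", values_to = "pa") |>
    mutate(modulus = ifelse(.data$modulus == "g_prime_pa", "G'", "G''"))
  ggplot(df, aes(x = .data$frequency_hz, y = .data$pa,
                 color = .data$modulus, group = interaction(.data$modulus, .data$replicate))) +
    geom_line(alpha = 0.7) +
    geom_vline(xintercept = frequency_hz, linetype = 2, color = "grey50") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "frequency (Hz)", y = "modulus (Pa)", color = NULL) +
    theme_minimal()
}
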