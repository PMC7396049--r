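#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$z_center, .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "z (Å)", y = "water density (waters/Å)",
                  title = "Water density along the channel axis") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!.data$masked)
  ggplot2::ggplot(df, ggplot2::aes(.data$z_center, .data$dG)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dG - .data$error,
                                      ymax = .data$dG + .data$error),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "z (Å)", y = expression(Delta * G ~ "(kcal/mol)"),
                  title = "Free-energy profile (Boltzmann inversion)",
                  subtitle = sprintf("reference z_A = %.1f Å, band ± kBT",
                                     attr(object, "z_A"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pore_profile <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!.data$masked)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$z_center, .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "pore radius (Å)",
                  title = "Pore-radius profile") +
    ggplot2::theme_minimal()
  if (is.finite(attr(object, "sf_z"))) {
    p <- p + ggplot2::annotate("point", x = attr(object, "sf_z"),
                               y = attr(object, "sf_radius"),
                               shape = 4, size = 3) +
      ggplot2::annotate("text", x = attr(object, "sf_z"),
                        y = attr(object, "sf_radius"),
                        label = "SF", vjust = -1)
  }
  p
}

#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "RMSD (Å)",
                  title = sprintf("RMSD (%s, %s)", attr(object, "selection"),
                                  if (isTRUE(attr(object, "fitted")))
                                    "superposed" else "no fit")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.single_file_report <- function(object, ...) {
  ggplot2::ggplot(strip_profile_class(object),
                  ggplot2::aes(.data$time, .data$n_file)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ps)", y = "single-file waters in channel",
                  title = "Single-file chain occupancy") +
    ggplot2::theme_minimal()
}
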