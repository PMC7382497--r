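#' Plot a drive trajectory
#'
#' Stacked queen densities by genotype over generations: light blue for
#' wild-type (`ww`), gold for heterozygous carriers (`wi`), dark blue for
#' homozygous carriers (`ii`).
#'
#' @param object A `drive_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drive_trajectory <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::group_by(.data$generation, .data$genotype) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop") |>
    dplyr::mutate(genotype = factor(.data$genotype,
                                    levels = c("ww", "wi", "ii")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$density,
                                     fill = .data$genotype)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_manual(
      values = c(ww = "#9ecae1", wi = "#d4af37", ii = "#08306b"),
      labels = c(ww = "wild-type", wi = "heterozygous", ii = "homozygous")) +
    ggplot2::labs(x = "generation (years)",
                  y = expression(queens~km^-2), fill = "queen genotype") +
    ggplot2::theme_minimal()
}

#' Plot a phase scan
#'
#' Tile map of the homing x sterility grid coloured by long-run
#' suppression, with the eradication region outlined.
#'
#' @param object A `drive_scan` from [phase_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drive_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$p)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$suppression_pct)) +
    ggplot2::geom_point(data = df[df$eradicated, ], size = 0.3,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "suppression (%)") +
    ggplot2::labs(x = "homing rate h", y = "drone sterility p",
                  caption = "white dots: eradication within horizon") +
    ggplot2::theme_minimal()
}

#' Plot a stochastic ensemble
#'
#' Per-replicate total-density trajectories (thin lines) with the
#' ensemble mean (thick line).
#'
#' @param object A `drive_ensemble` from [stochastic_simulate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drive_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$generation, y = .data$total,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(y = .data$mean_total, group = NULL),
                       colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "generation (years)",
                  y = expression(queens~km^-2)) +
    ggplot2::theme_minimal()
}
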