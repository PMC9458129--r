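#' Plot a single-cell trajectory
#'
#' Species time courses on the hourly grid; by default the two readouts the
#' fate calls are based on (cPARP and free cytosolic Smac).
#'
#' @param object A `cell_trajectory`.
#' @param species Character vector of species to show.
#' @param log_y Log-scale the amount axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_trajectory <- function(object, species = c("cPARP", "Smac_cyto"),
                                     log_y = FALSE, ...) {
  d <- dplyr::filter(tidy(object), .data$species %in% !!species)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$amount,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "amount (molecules/cell)",
                  title = object$condition$label) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a population result
#'
#' Histogram of per-cell apoptosis times with the viable (never-crossing)
#' fraction annotated.
#'
#' @param object A `population_result`.
#' @param binwidth Hours per bin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_result <- function(object, binwidth = 1, ...) {
  d <- tidy(object)
  v <- attr(object, "viability_percent")
  ggplot2::ggplot(dplyr::filter(d, .data$apoptotic),
                  ggplot2::aes(x = .data$apoptosis_time_h)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "firebrick", colour = "white") +
    ggplot2::labs(x = "apoptosis time (h)", y = "cells",
                  title = attr(object, "condition")$label,
                  subtitle = sprintf("viability %.1f%% of %d cells", v, nrow(d))) +
    ggplot2::theme_minimal()
}

#' Plot a one-phase-decay fit
#'
#' Observed viabilities and the fitted decay curve.
#'
#' @param object A `decay_fit`.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = n_grid))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "calcium (uM)", y = "viability (%)") +
    ggplot2::theme_minimal()
}
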