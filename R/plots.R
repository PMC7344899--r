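## ggplot2 displays of the analysis results.

#' Plot a melting curve
#'
#' Global contact index against temperature with three-segment error bars.
#'
#' @param object A [melting_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot melting_curve
#' @export
autoplot.melting_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature, y = .data$gci)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gci - .data$segment_sd,
                                        ymax = .data$gci + .data$segment_sd),
                           width = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (K)", y = "Global contact index") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
}

#' Plot a melting-temperature fit
#'
#' The measured melting curve with the fitted logistic overlaid and the
#' fitted Tm marked.
#'
#' @param object A `melt_fit` from [fit_melting_temperature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$temperature, y = .data$gci)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Temperature (K)", y = "Global contact index",
                  subtitle = sprintf("Tm = %.1f K (%s)", object$tm, object$method)) +
    ggplot2::theme_minimal()
  if (object$method == "logistic") {
    grid <- tibble(temperature = seq(min(curve$temperature),
                                     max(curve$temperature), length.out = 200))
    grid$gci <- .logistic4(grid$temperature, object$upper, object$lower,
                           object$tm, object$steepness)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Per-residue contact profile across the temperature ladder
#'
#' One line per temperature (cold blue to hot red), residue on the x axis —
#' the standard residue-resolved view of where along the sequence the
#' peptide engages the membrane.
#'
#' @param matrices List of per-temperature [contact_matrix()] objects.
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(matrices) {
  df <- purrr::map_dfr(matrices, residue_contact_index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$index,
                                   colour = .data$temperature,
                                   group = .data$temperature)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_gradient(low = "darkblue", high = "darkred",
                                   name = "T (K)") +
    ggplot2::labs(x = "Residue", y = "Contact index") +
    ggplot2::theme_minimal()
}

#' Bar chart of TAGCI values across constructs
#'
#' @param tagci_table Tibble with columns `construct` and `tagci` (rows from
#'   [tagci()]).
#' @return A ggplot object.
#' @export
plot_tagci <- function(tagci_table) {
  df <- dplyr::mutate(tagci_table,
                      construct = factor(.data$construct,
                                         levels = unique(.data$construct)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$construct, y = .data$tagci)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "TAGCI") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
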