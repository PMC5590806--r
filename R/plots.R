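#' Plot a ventral-to-dorsal intensity profile
#'
#' @param object A `dv_profile`.
#' @param ... Unused.
#' @return A ggplot: mean intensity vs angle with a +/- 1 sd ribbon.
#' @method autoplot dv_profile
#' @export
autoplot.dv_profile <- function(object, ...) {
  df <- object[!is.na(object$mean), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
                   ymax = .data$mean + dplyr::coalesce(.data$sd, 0)),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "angle from ventral (degrees)",
                  y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot the final concentration fields of a simulation
#'
#' @param object A `dv_sim`.
#' @param ... Unused.
#' @return A ggplot of each species' final profile along the axis.
#' @method autoplot dv_sim
#' @export
autoplot.dv_sim <- function(object, ...) {
  if (!object$success) abort("Cannot plot a failed simulation.")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x, y = .data$concentration,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (um, ventral to dorsal)",
                  y = "concentration (nM)", colour = NULL,
                  title = paste("genotype:", object$genotype)) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP recovery curve
#'
#' @param object A `frap_curve`.
#' @param ... Unused.
#' @return A ggplot of mean masked intensity vs time.
#' @method autoplot frap_curve
#' @export
autoplot.frap_curve <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$intensity), ],
                  ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot mechanism label counts of a classified screen
#'
#' @param object A `dv_classification`.
#' @param ... Unused.
#' @return A ggplot bar chart of labels among solutions passing all gates.
#' @method autoplot dv_classification
#' @export
autoplot.dv_classification <- function(object, ...) {
  fitted <- object[object$pass_all, , drop = FALSE]
  ggplot2::ggplot(fitted, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fitted solutions") +
    ggplot2::theme_minimal()
}
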