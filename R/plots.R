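#' Plot the F_IS trajectory of an exact propagation
#'
#' Mean F_IS over generations with the central 95% band of the exact
#' per-generation F_IS distribution.
#'
#' @param object A `state_trajectory` from [propagate()].
#' @param exclude Passed to [fis_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_trajectory
#' @export
autoplot.state_trajectory <- function(object, exclude = "fixed", ...) {
  tab <- tidy(object, exclude = exclude)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5,
                                      ymax = .data$q97.5),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_fis)) +
    ggplot2::labs(x = "generation", y = expression(F[IS])) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Plot states or distributions in the de Finetti triangle
#'
#' Points are genotype-frequency states projected into the ternary
#' triangle; for a distribution source the point size follows the
#' probability weight. The Hardy-Weinberg parabola (F_IS = 0) is drawn as
#' a reference.
#'
#' @param object A `definetti_df` from [definetti_coords()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot definetti_df
#' @export
autoplot.definetti_df <- function(object, ...) {
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, linewidth = 0.3) +
    ggplot2::geom_path(data = hwe_parabola(), linetype = "dashed",
                       colour = "grey50")
  p <- if ("weight" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                            alpha = 0.6) +
      ggplot2::scale_size_area(max_size = 3)
  } else {
    p + ggplot2::geom_point(size = 0.4, alpha = 0.6)
  }
  p + ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the parameter-space dominance map
#'
#' Tiles the (c, mu) grid by the dominant evolutionary process.
#'
#' @param object A [phase_diagram()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c, y = .data$mu,
                                       fill = .data$dominant)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rate of clonality c", y = "mutation rate μ",
                  fill = "dominant\nprocess") +
    ggplot2::theme_minimal()
}
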