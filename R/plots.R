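# ggplot2 views of morphologies and parameter distributions.

#' Plot a morphology
#'
#' Draws the dendritic tree as segments in the transverse (x-y) and
#' longitudinal (z-y) projections, line width proportional to local
#' diameter.
#'
#' @param object A [morphology][as_morphology].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morphology <- function(object, ...) {
  pr <- parent_row(object)
  has_p <- !is.na(pr)
  seg <- tibble::tibble(
    x = object$x[has_p], y = object$y[has_p], z = object$z[has_p],
    xend = object$x[pr[has_p]], yend = object$y[pr[has_p]],
    zend = object$z[pr[has_p]],
    diameter = 2 * object$radius[has_p]
  )
  long <- dplyr::bind_rows(
    dplyr::transmute(seg, plane = "transverse (x-y)",
      h = .data$x, v = .data$y, hend = .data$xend, vend = .data$yend,
      diameter = .data$diameter
    ),
    dplyr::transmute(seg, plane = "longitudinal (z-y)",
      h = .data$z, v = .data$y, hend = .data$zend, vend = .data$yend,
      diameter = .data$diameter
    )
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$h, y = .data$v, xend = .data$hend, yend = .data$vend,
        linewidth = .data$diameter
      ),
      lineend = "round"
    ) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 1.5), guide = "none") +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(mu * m), y = expression(mu * m)) +
    ggplot2::theme_minimal()
}

#' Compare basic-parameter distributions of two populations
#'
#' Overlaid density histograms of extracted basic parameters, e.g. a
#' generated population against the reference reconstruction set — the
#' visual companion of the per-parameter KS comparison.
#'
#' @param basic,reference Tidy tables from [extract_basic()].
#' @param parameters Which parameters to show (default
#'   [directly_drawn_parameters()]).
#' @return A ggplot object, faceted by parameter.
#' @export
plot_basic_comparison <- function(basic, reference,
                                  parameters = directly_drawn_parameters()) {
  both <- dplyr::bind_rows(
    dplyr::mutate(basic, set = "generated"),
    dplyr::mutate(reference, set = "reference")
  )
  both <- dplyr::filter(both, .data$parameter %in% parameters, !is.na(.data$value))
  ggplot2::ggplot(both, ggplot2::aes(.data$value, fill = .data$set)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      position = "identity", alpha = 0.5, bins = 30
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "probability density", fill = NULL) +
    ggplot2::theme_minimal()
}
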