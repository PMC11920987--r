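#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a probability mass vector
#'
#' @param object A `pmv` tibble from [predict_pmv()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmv
#' @export
autoplot.pmv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$polar_deg, .data$prob)) +
    ggplot2::geom_col(width = diff(object$polar_deg[1:2]) * 0.9) +
    ggplot2::labs(x = "polar angle (deg)", y = "response probability")
}

#' Plot a spectral weighting scheme
#'
#' @param object A [weighting_scheme()].
#' @param ... Unused.
#' @return A ggplot of weight versus band center frequency (log axis).
#' @method autoplot weighting_scheme
#' @export
autoplot.weighting_scheme <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cf_hz, .data$weight)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "band center frequency (Hz)", y = "weight",
                  title = attr(object, "scheme_name"))
}

#' Plot protected exceedance probabilities
#'
#' @param object An `rfx_result` from [rfx_group_inference()].
#' @param ... Unused.
#' @return A ggplot bar chart of PXP per variant, annotated with the BOR.
#' @method autoplot rfx_result
#' @export
autoplot.rfx_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$variant, .data$pxp)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "protected exceedance probability",
                  x = NULL,
                  subtitle = sprintf("BOR = %.3g", object$bor))
}

#' Heatmap of model PMVs with response overlay
#'
#' Figure-style summary of one listener and plane: predicted response
#' probability (brightness) over target and response polar angles, with the
#' actual (or simulated) responses overlaid as open circles.
#'
#' @param templates A [template_set()].
#' @param params A [model_params()].
#' @param scheme A [weighting_scheme()].
#' @param responses Optional response tibble to overlay.
#' @param lateral_plane Plane to display.
#' @param phi_scale Binaural weighting scale (deg).
#' @return A ggplot.
#' @export
plot_pmv_heatmap <- function(templates, params, scheme, responses = NULL,
                             lateral_plane = 0, phi_scale = 13) {
  p <- template_plane(templates, lateral_plane)
  tg <- tibble::tibble(lat = lateral_plane, pol = p$theta)
  m <- pmv_matrix(templates, tg, params, scheme, lateral_plane, phi_scale)
  df <- tibble::tibble(target = rep(tg$pol, each = length(m$theta)),
                       response = rep(m$theta, nrow(tg)),
                       prob = as.numeric(m$pmv))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$response)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "target polar angle (deg)",
                  y = "response polar angle (deg)", fill = "p")
  if (!is.null(responses))
    g <- g + ggplot2::geom_point(
      data = responses,
      ggplot2::aes(.data$target_pol, .data$response_pol),
      shape = 1, colour = "red", inherit.aes = FALSE)
  g
}
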