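# ggplot2 views of the main result types.

#' Plot a fitted foci-kinetics model over the data
#'
#' Data points with their between-replicate error bars, overlaid with the
#' fitted model curve, facetted by dataset.
#'
#' @param object A `foci_fit`.
#' @param t_n Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot foci_fit
#' @export
autoplot.foci_fit <- function(object, t_n = 100, ...) {
  curves <- fitted_curves(
    object,
    exp(seq(log(min(object$data$t_h)), log(max(object$data$t_h)),
            length.out = t_n))
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_h, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      size = 0.3
    ) +
    ggplot2::geom_line(data = curves, colour = "#2166ac") +
    ggplot2::facet_wrap(~quality, scales = "free_y") +
    ggplot2::labs(x = "time post irradiation (h)",
                  y = "mean foci per nucleus")
}

#' Plot robustness envelopes
#'
#' The per-quality min/max band of the fitted model curves across the
#' variant sweep, with the default-variant curve.
#'
#' @param object A `variant_sweep` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_sweep
#' @export
autoplot.variant_sweep <- function(object, ...) {
  ggplot2::ggplot(object$envelope, ggplot2::aes(x = .data$t_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$default), colour = "#2166ac") +
    ggplot2::facet_wrap(~quality, scales = "free_y") +
    ggplot2::labs(x = "time post irradiation (h)",
                  y = "mean foci per nucleus")
}

#' Plot a track-cluster spectrum
#'
#' Mean number of clusters per nucleus against cluster multiplicity.
#'
#' @param spectrum Tibble from [estimate_cluster_spectrum()] (one or more
#'   qualities).
#' @return A ggplot object.
#' @export
plot_cluster_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = factor(.data$n), y = .data$k_bar)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~quality) +
    ggplot2::labs(x = "tracks per cluster", y = "mean clusters per nucleus")
}
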