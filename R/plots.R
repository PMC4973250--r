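#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an abundance spectrum on log-log axes
#'
#' @param object An [spectrum_from_counts()] tibble (may hold several k).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abundance_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$n,
                                       colour = factor(.data$k))) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance s", y = expression(n[k](s)),
                  colour = "k") +
    ggplot2::theme_minimal()
}

#' Plot a log-binned spectrum
#'
#' @param object A [log_bin()] tibble.
#' @param ... Unused.
#' @return A ggplot of density versus bin centre on log-log axes.
#' @export
autoplot.binned_spectrum <- function(object, ...) {
  pos <- object[object$density > 0, ]
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$center, y = .data$density,
                                    colour = factor(.data$k))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance s (bin centre)", y = "density",
                  colour = "k") +
    ggplot2::theme_minimal()
}

#' Plot a Hill exponent curve, optionally with the analytic fit
#'
#' @param object An [exponent_curve()] tibble.
#' @param fit Optional [fit_ratio()] result to overlay.
#' @param ... Unused.
#' @return A ggplot of `alpha_hat` versus `k` with +-2 SE error bars.
#' @export
autoplot.exponent_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$alpha_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$alpha_hat - 2 * .data$se,
      ymax = .data$alpha_hat + 2 * .data$se)) +
    ggplot2::labs(x = "k-mer length k", y = expression(hat(alpha)(k))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    kk <- seq(min(object$k), max(object$k), length.out = 200)
    pred <- tibble::tibble(k = kk,
                           alpha_hat = alpha_of_k(kk, ratio = fit$ratio_hat))
    p <- p + ggplot2::geom_line(data = pred, colour = "firebrick")
  }
  p
}

#' @export
plot.burst_tree <- function(x, ...) {
  ape::plot.phylo(ape::as.phylo(x), ...)
}
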