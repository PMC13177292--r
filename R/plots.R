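# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.batman_fit <- function(object, ...) {
  area <- trapz_int(object$data$time, pmax(object$data$intensity, 0))
  d <- dplyr::bind_rows(
    tibble::tibble(time = object$data$time,
                   intensity = object$data$intensity / area, what = "data"),
    dplyr::mutate(object$fitted, what = "fit"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$intensity,
                                  colour = .data$what)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(data = "grey40", fit = "firebrick")) +
    ggplot2::labs(x = "time (min)", y = "normalised signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Eyring-Polanyi diagnostic plot of a rate table
#'
#' `ln(k/T)` against `1000/T`, optionally coloured by a grouping column.
#'
#' @param tbl Tibble with `temperature`, `k` and optionally `se`.
#' @param colour Optional bare column name for colouring.
#' @return A ggplot.
#' @export
plot_eyring <- function(tbl, colour = NULL) {
  tbl <- dplyr::filter(tbl, .data$k > 0)
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = 1000 / .data$temperature,
                                         y = log(.data$k / 60 / .data$temperature),
                                         colour = {{ colour }})) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = expression(1000 / T ~ (K^-1)),
                  y = expression(ln(k / T))) +
    ggplot2::theme_minimal()
  if ("se" %in% names(tbl)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = log(pmax(.data$k - .data$se, 1e-12) / 60 / .data$temperature),
                   ymax = log((.data$k + .data$se) / 60 / .data$temperature)),
      width = 0)
  }
  p
}

#' Residual diagnostics of the mixed-effects decomposition
#'
#' Weighted residuals against fitted values and a normal Q-Q panel.
#'
#' @param mem A [fit_phase_mem()] object.
#' @return A ggplot (two facets).
#' @export
plot_mem_diagnostics <- function(mem) {
  d <- tibble::tibble(fitted = stats::fitted(mem$fit),
                      resid = stats::resid(mem$fit, scaled = TRUE))
  qq <- stats::qqnorm(d$resid, plot.it = FALSE)
  dd <- dplyr::bind_rows(
    tibble::tibble(x = d$fitted, y = d$resid, panel = "residuals vs fitted"),
    tibble::tibble(x = qq$x, y = qq$y, panel = "normal Q-Q"))
  ggplot2::ggplot(dd, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
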