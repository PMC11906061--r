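# ggplot2 methods for the package's result types

#' Plot a Sine-G distribution
#'
#' Density, hazard, survival and cumulative-hazard curves of a
#' [sine_dist()] on a time grid (default: up to the 99.5% quantile).
#'
#' @param object A [sine_dist()].
#' @param t Optional time grid.
#' @param which Functions to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sine_dist
#' @export
autoplot.sine_dist <- function(object, t = NULL,
                               which = c("pdf", "hrf", "sf", "chrf"), ...) {
  if (is.null(t)) {
    t <- seq(0, sine_quantile(object, 0.995), length.out = 200)
  }
  df <- sine_curves(object, t)
  df <- tidyr::pivot_longer(df, -"t", names_to = "fn", values_to = "value")
  df <- dplyr::filter(df, .data$fn %in% which)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::labs(title = format(object), x = "t", y = NULL)
}

#' Trace and density plots for a Bayesian fit
#'
#' @param object A `sine_ph_bayes` object.
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot faceted by parameter (chains coloured).
#' @method autoplot sine_ph_bayes
#' @export
autoplot.sine_ph_bayes <- function(object, type = c("trace", "density"),
                                   ...) {
  type <- match.arg(type)
  df <- posterior_draws(object)
  df <- tidyr::pivot_longer(df, -c(".chain", ".iteration"),
                            names_to = "term", values_to = "value")
  df$.chain <- factor(df$.chain)
  if (type == "trace") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                     colour = .data$.chain)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL, colour = "chain")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                     colour = .data$.chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density", colour = "chain")
  }
}

#' TTT plot
#'
#' Scaled total-time-on-test transform against `r/n` with the diagonal for
#' reference; concavity above the diagonal indicates an increasing hazard.
#'
#' @param object A [ttt_statistic()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ttt_statistic
#' @export
autoplot.ttt_statistic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$ttt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "r/n", y = "scaled TTT")
}

#' Model-comparison dot plot
#'
#' @param object A [compare_models()] result.
#' @param criterion Criterion column to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sinegph_comparison
#' @export
autoplot.sinegph_comparison <- function(object, criterion = "waic", ...) {
  df <- dplyr::mutate(object,
                      model = stats::reorder(.data$model,
                                             -.data[[criterion]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[criterion]],
                                   y = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = toupper(criterion), y = NULL)
}
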