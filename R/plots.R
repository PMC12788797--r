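#' Plot a diffusion spectrum
#'
#' Occupation mass per diffusion coefficient on a log axis, with the
#' chromatin-bound region (D below the threshold) shaded.
#'
#' @param object a `diffusion_spectrum`.
#' @param threshold bound-fraction cutoff to shade, um^2/s.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot diffusion_spectrum
#' @export
autoplot.diffusion_spectrum <- function(object, threshold = 0.1, ...) {
  df <- object$spectrum
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D, y = .data$occupation)) +
    ggplot2::annotate("rect", xmin = min(df$D), xmax = threshold,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)), y = "occupation",
                  subtitle = sprintf("bound fraction (D < %g) = %.3f",
                                     threshold, bound_fraction(object, threshold))) +
    ggplot2::theme_minimal()
}

#' Plot variance-decomposition curves
#'
#' Trial s.d. against subsample size on log-log axes, one line per sampling
#' scheme; the heights of the cell/day plateaus read out the corresponding
#' variance components.
#'
#' @param object a `variance_curves` tibble from [variance_decomposition()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot variance_curves
#' @export
autoplot.variance_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$sd,
                                       colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "jumps subsampled (n)", y = "s.d. of trial statistic") +
    ggplot2::theme_minimal()
}

#' Plot a FRAP recovery curve
#'
#' @param object a `frap_curve` or `frap_curve_binned`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot frap_curve
#' @export
autoplot.frap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "time since bleach (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.frap_curve
#' @method autoplot frap_curve_binned
#' @export
autoplot.frap_curve_binned <- autoplot.frap_curve

#' Plot a FRAP fit over its binned data
#'
#' @param object a `frap_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  tt <- exp(seq(log(min(d$time)), log(max(d$time)), length.out = 200))
  fit_df <- tibble::tibble(time = tt, value = object$fitted(tt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit_df, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time since bleach (s)", y = "FRAP(t)",
                  subtitle = sprintf("%s-exponential, rss = %.3g",
                                     object$model, object$rss)) +
    ggplot2::theme_minimal()
}
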