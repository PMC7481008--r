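# ggplot2 views of the result objects. Each autoplot returns a plain
# ggplot for further styling.

#' @export
autoplot.rate_posterior <- function(object, level = 0.95, n_grid = 400,
                                    ...) {
  ci <- credible_interval(object, level)
  kmax <- qgamma(0.999, object$shape, rate = object$theta)
  grid <- tibble(k = seq(0, kmax, length.out = n_grid))
  grid$density <- posterior_density(object, grid$k)
  shade <- grid[grid$k >= ci$low & grid$k <= ci$high, ]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$k, y = .data$density)) +
    ggplot2::geom_area(data = shade, fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = posterior_mean(object),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("rate k (1/%s)", object$time_unit),
      y = "posterior density",
      title = sprintf("%s-prior rate posterior (n = %d)", object$prior,
                      object$n))
}

#' @export
autoplot.survival_estimate <- function(object, ...) {
  tmax <- max(object$curve$time)
  fit <- tibble(time = seq(0, tmax, length.out = 200))
  fit$survival <- exp(-fit$time / object$tau)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(data = fit, colour = "firebrick",
                       linetype = "dashed") +
    ggplot2::labs(x = sprintf("time (%s)", object$time_unit),
                  y = "survival fraction S(t)",
                  title = sprintf("exponential fit: t1/2 = %.3g %s",
                                  object$half_life, object$time_unit))
}

#' @export
autoplot.sample_size_curve <- function(object, ...) {
  ok <- !object$degenerate & object$se > 0
  ggplot2::ggplot(object[ok, ],
                  ggplot2::aes(x = .data$size, y = .data$se)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample size N", y = "standard error",
                  title = sprintf("SE scaling exponent %.3f",
                                  attr(object, "scaling_exponent")))
}

#' @export
autoplot.fe_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$dg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dg - .data$se,
                                      ymax = .data$dg + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate",
                  y = sprintf("free energy (kt = %g)", attr(object, "kt")))
}

#' @export
autoplot.acf_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag", y = "autocorrelation",
                  title = sprintf("statistical inefficiency g = %.3g",
                                  object$inefficiency))
}

#' @export
autoplot.rdf_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60",
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r", y = "g(r)",
                  title = sprintf("%s normalization",
                                  attr(object, "normalization")))
}

#' @export
autoplot.work_set <- function(object, ...) {
  df <- as_tibble(object)
  df$work_plot <- ifelse(df$direction == "reverse", -df$work, df$work)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$work_plot,
                                   fill = .data$direction)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity",
                            bins = 40) +
    ggplot2::labs(x = "work (kJ/mol; reverse negated)", y = "count",
                  title = "forward / negated-reverse work distributions")
}
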