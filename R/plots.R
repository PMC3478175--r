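#' Plot an avalanche size distribution on log-log axes
#'
#' @param object A [size_distribution()].
#' @param fit Optional `powerlaw_fit` whose regression line (over its fit
#'   range) is overlaid.
#' @param ... Unused.
#' @return A ggplot object: occurrence probability against size, both
#'   axes log10.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$size, y = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "avalanche size", y = "occurrence probability") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "powerlaw_fit"))
    line <- tibble::tibble(
      size = c(fit$fit_min, fit$fit_max),
      probability = 10^(fit$intercept + fit$alpha * log10(c(fit$fit_min, fit$fit_max))))
    p <- p +
      ggplot2::geom_line(data = line, colour = "red") +
      ggplot2::labs(subtitle = sprintf("alpha = %.3f, R^2 = %.3f",
                                       fit$alpha, fit$r_squared))
  }
  p
}

#' Plot a power-law fit over its size distribution points
#'
#' @param object A `powerlaw_fit` from [fit_powerlaw()].
#' @param ... Unused.
#' @return A ggplot object: the fitted log-log points with the regression
#'   line and the alpha / R-squared annotation.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  line <- tibble::tibble(
    size = c(object$fit_min, object$fit_max),
    probability = 10^(object$intercept +
                        object$alpha * log10(c(object$fit_min, object$fit_max))))
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$size, y = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "avalanche size", y = "occurrence probability",
                  subtitle = sprintf("alpha = %.3f, R^2 = %.3f (%s)",
                                     object$alpha, object$r_squared,
                                     if (object$accepted) "accepted" else "rejected")) +
    ggplot2::theme_minimal()
}

#' Plot group-mean alpha with SEM error bars
#'
#' @param object An `avalanche_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object: per-condition mean alpha with SEM bars and
#'   the per-session values overplotted.
#' @method autoplot avalanche_study
#' @export
autoplot.avalanche_study <- function(object, ...) {
  usable <- dplyr::filter(object$sessions, .data$accepted)
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$condition, y = .data$mean_alpha)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_alpha - .data$sem_alpha,
                   ymax = .data$mean_alpha + .data$sem_alpha),
      width = 0.2) +
    ggplot2::geom_jitter(data = usable,
                         ggplot2::aes(x = .data$condition, y = .data$alpha),
                         width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "alpha (log-log slope)") +
    ggplot2::theme_minimal()
}
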