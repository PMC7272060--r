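#' Plot period-level abundance estimates
#'
#' Point estimates with +/- 1 SE error bars per period, coloured by survey
#' method.
#'
#' @param estimates Tibble from [lp_period_estimates()].
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$period_id, y = .data$n_hat,
                               colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$n_hat - .data$se,
                                          ymax = .data$n_hat + .data$se),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "Lincoln-Petersen estimate",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Plot cumulative-sampling precision
#'
#' Cumulative Lincoln-Petersen estimates with 95% jackknife intervals
#' against the number of pooled surveys — the visual check that estimates
#' and variances stabilise after a few repeated surveys.
#'
#' @param cumulative Tibble from [cumulative_estimates()] (rows from one or
#'   more period/method combinations may be bound together).
#' @return A ggplot object.
#' @export
plot_cumulative <- function(cumulative) {
  ggplot2::ggplot(cumulative,
                  ggplot2::aes(x = .data$k, y = .data$n_hat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$period_id + .data$method, scales = "free_y") +
    ggplot2::labs(x = "Pooled surveys (k)",
                  y = "Cumulative Lincoln-Petersen estimate") +
    ggplot2::theme_minimal()
}

#' Posterior densities of the per-method marked proportion
#'
#' @param object A `detection_fit`.
#' @param ... Unused.
#' @return A ggplot object: one density per method with the posterior
#'   median marked.
#' @method autoplot detection_fit
#' @export
autoplot.detection_fit <- function(object, ...) {
  dr <- purrr::map_dfr(object$methods, function(m) {
    eta <- object$draws$alpha
    if (m != object$reference) eta <- eta + object$draws[[paste0("beta_", m)]]
    tibble(method = m, proportion = plogis(eta))
  })
  med <- dr %>% group_by(.data$method) %>%
    summarise(m = stats::median(.data$proportion), .groups = "drop")
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = med, ggplot2::aes(xintercept = .data$m),
                        colour = "blue") +
    ggplot2::facet_wrap(~ .data$method, ncol = 1) +
    ggplot2::labs(x = "Modelled proportion of detections that are marked",
                  y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a historical series with converted estimates
#'
#' @param adjusted Tibble from [apply_conversion()].
#' @return A ggplot object showing the original and rescaled series.
#' @export
plot_conversion_series <- function(adjusted) {
  long <- tidyr::pivot_longer(adjusted, c("n_hat", "n_hat_adjusted"),
                              names_to = "series", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$estimate,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(labels = c(n_hat = "as surveyed",
                                              n_hat_adjusted = "converted")) +
    ggplot2::labs(x = "Year", y = "Abundance estimate", colour = NULL) +
    ggplot2::theme_minimal()
}
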