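#' Plot a posterior exposure-response curve
#'
#' Mean predicted pollutant change across the SI range with its credible
#' band; optionally overlays thin per-city curves behind the average, the
#' way multi-city exposure-response figures are usually drawn.
#'
#' @param object A `pollution_fit`.
#' @param si_grid SI grid, default 0-80.
#' @param cities Plot thin city-specific curves behind the average.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pollution_fit
#' @export
autoplot.pollution_fit <- function(object, si_grid = 0:80, cities = TRUE,
                                   ...) {
  avg <- predict_curve(object, si_grid, "average")
  p <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$si, y = .data$estimate))
  if (cities) {
    city_curves <- purrr::map(
      object$cities$city_id,
      ~ suppressWarnings(predict_curve(object, si_grid, .x))
    ) %>% bind_rows()
    p <- p + ggplot2::geom_line(
      data = city_curves,
      ggplot2::aes(group = .data$city_id),
      colour = "grey80", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Stringency Index (%)",
      y = expression(paste("Change in concentration (", mu, "g/", m^3, ")")),
      title = object$pollutant
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot policy_fit
#' @export
autoplot.policy_fit <- autoplot.pollution_fit

#' Plot per-policy effect estimates
#'
#' Forest-style plot of the posterior mean effect of each policy's
#' maximum level, with 95% credible intervals, per pollutant.
#'
#' @param effects Output of [run_all_policies()] (possibly row-bound
#'   across pollutants).
#' @return A ggplot object.
#' @export
plot_policy_effects <- function(effects) {
  ggplot2::ggplot(
    effects,
    ggplot2::aes(x = .data$policy_id, y = .data$alpha_mean)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~pollutant, scales = "free_y") +
    ggplot2::labs(
      x = "Policy indicator",
      y = expression(paste("Effect at maximum level (", mu, "g/", m^3, ")"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot city burden totals
#'
#' @param burden A `burden_result` with Monte-Carlo intervals.
#' @param top_n Show the `top_n` cities by absolute burden.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, top_n = 20) {
  ct <- burden$city_totals %>%
    arrange(.data$total) %>%
    filter(rank(-abs(.data$total)) <= top_n)
  ggplot2::ggplot(
    ct,
    ggplot2::aes(x = stats::reorder(.data$city_id, .data$total),
                 y = .data$total)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      colour = "firebrick"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = paste0("Attributable deaths (", burden$pollutant,
                 ", Feb-Jul; negative = avoided)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
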