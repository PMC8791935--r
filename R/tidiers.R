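#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of a stringency exposure-response fit
#'
#' One row per model term: the four fixed spline coefficients, the two
#' covariate coefficients, the residual standard deviation, and the
#' Matern hyperparameters (range in km, marginal sd) of each spatial
#' field.
#'
#' @param x A `pollution_fit`.
#' @param level Credible level for the intervals.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `lo`, `hi`.
#' @method tidy pollution_fit
#' @export
tidy.pollution_fit <- function(x, level = 0.95, ...) {
  summarize_draws <- function(term, draws, estimate = mean(draws)) {
    ci <- empirical_ci(draws, level = level)
    tibble(term = term, estimate = estimate, lo = ci[1], hi = ci[2])
  }
  bd <- beta_draws(x)
  out <- purrr::map(1:4, function(k) {
    summarize_draws(sprintf("beta%d", k), bd[, k],
                    x$coef_mean[x$cols$beta[k]])
  })
  cov_draws <- x$coef_draws[, x$cols$cov, drop = FALSE]
  out <- c(out, list(
    summarize_draws("gamma_ndvi", cov_draws[, 1], x$coef_mean[x$cols$cov[1]]),
    summarize_draws("gamma_builtup", cov_draws[, 2], x$coef_mean[x$cols$cov[2]]),
    summarize_draws("residual_sd", x$sigma_draws)
  ))
  n_fields <- (ncol(x$theta_draws) - 1L) / 2L
  field_names <- c(sprintf("b%d", 1:4), if (n_fields == 5) "a")
  for (k in seq_len(n_fields)) {
    out <- c(out, list(
      summarize_draws(paste0("matern_range_", field_names[k]),
                      exp(x$theta_draws[, 2 * k])),
      summarize_draws(paste0("matern_sd_", field_names[k]),
                      exp(x$theta_draws[, 2 * k + 1]))
    ))
  }
  if (inherits(x, "policy_fit")) {
    out <- c(out, list(
      summarize_draws("alpha", x$coef_draws[, x$cols$alpha],
                      x$coef_mean[x$cols$alpha])
    ))
  }
  bind_rows(out)
}

#' @rdname tidy.pollution_fit
#' @method tidy policy_fit
#' @export
tidy.policy_fit <- tidy.pollution_fit

#' One-line fit summary
#'
#' @param x A `pollution_fit`.
#' @param ... Unused.
#' @return A one-row tibble: pollutant, number of cities, posterior draws,
#'   mean residual sd, sampler acceptance rate and convergence flag.
#' @export
glance.pollution_fit <- function(x, ...) {
  tibble(
    pollutant = x$pollutant,
    n_cities = nrow(x$cities),
    n_draws = nrow(x$coef_draws),
    residual_sd = mean(x$sigma_draws),
    acceptance_rate = x$diagnostics$acceptance_rate,
    converged = x$diagnostics$converged
  )
}

#' Tidy a burden result
#'
#' @param x A `burden_result`.
#' @param ... Unused.
#' @return The per-city totals with the grand total as a closing row.
#' @method tidy burden_result
#' @export
tidy.burden_result <- function(x, ...) {
  bind_rows(
    x$city_totals,
    x$grand_total %>% mutate(city_id = "TOTAL", .before = 1)
  )
}
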