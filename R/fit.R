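# Assemble the no-intercept design matrix shared by the SI model and the
# per-policy model. Column blocks:
#   beta      4 anchored-spline columns (flat prior)
#   b_k       per spline coordinate k, one column per city: basis[, k] times
#             the city indicator (Matern spatial prior, own hyperparameters)
#   dow       6 sum-to-zero contrast columns per city (flat prior); the
#             sum-to-zero constraint keeps the interceptless model identified
#   ndvi_z, builtup_z  city-level covariates, z-scored across cities (flat)
#   alpha, a  optional standardized policy level: one global column plus one
#             spatially structured column per city
build_model_frame <- function(panel, si, cities, spec, policy_z = NULL) {
  validate_cities(cities)
  validate_pollution_panel(panel)
  if (length(unique(panel$pollutant)) != 1) {
    abort("Fit one pollutant per call.")
  }
  df <- panel %>%
    arrange(.data$city_id, .data$date) %>%
    left_join(si, by = c("city_id", "date"))
  if (any(is.na(df$si))) {
    abort("Misaligned panels: SI series does not cover every city-day.")
  }
  if (!all(df$city_id %in% cities$city_id)) {
    abort("Panel contains cities missing from the city table.")
  }
  if (!is.null(policy_z)) {
    df <- df %>% left_join(policy_z, by = c("city_id", "date"))
    if (any(is.na(df$z))) {
      abort("Misaligned panels: policy series does not cover every city-day.")
    }
  }
  cities <- cities %>% filter(.data$city_id %in% df$city_id)
  n_c <- nrow(cities)
  city_idx <- match(df$city_id, cities$city_id)
  dow <- as.POSIXlt(df$date)$wday + 1L
  basis <- build_spline_basis(df$si, spec, warn_extrapolation = FALSE)
  n <- nrow(df)

  Csum <- stats::contr.sum(7)

  blocks <- list()
  cols <- list()
  Xs <- list(beta = basis)
  cols$beta <- 1:4
  pos <- 4L
  for (k in 1:4) {
    Z <- matrix(0, n, n_c)
    Z[cbind(seq_len(n), city_idx)] <- basis[, k]
    Xs[[paste0("b", k)]] <- Z
    cols[[paste0("b", k)]] <- pos + seq_len(n_c)
    pos <- pos + n_c
  }
  D <- matrix(0, n, 6L * n_c)
  D[cbind(rep(seq_len(n), 6), (city_idx - 1L) * 6L + rep(1:6, each = n))] <-
    as.vector(Csum[dow, ])
  Xs$dow <- D
  cols$dow <- pos + seq_len(6L * n_c)
  pos <- pos + 6L * n_c
  ndvi_z <- as.numeric(scale(cities$ndvi))[city_idx]
  builtup_z <- as.numeric(scale(cities$builtup))[city_idx]
  Xs$cov <- cbind(ndvi_z, builtup_z)
  cols$cov <- pos + 1:2
  pos <- pos + 2L
  if (!is.null(policy_z)) {
    if (all(df$z == 0)) {
      abort(paste0(
        "Degenerate design: the policy is never implemented in the data ",
        "(z is 0 on every city-day)."
      ))
    }
    Xs$alpha <- matrix(df$z, ncol = 1)
    cols$alpha <- pos + 1L
    pos <- pos + 1L
    A <- matrix(0, n, n_c)
    A[cbind(seq_len(n), city_idx)] <- df$z
    Xs$a <- A
    cols$a <- pos + seq_len(n_c)
    pos <- pos + n_c
  }
  X <- do.call(cbind, unname(Xs))
  dist <- haversine_km(cities)
  spatial <- lapply(paste0("b", 1:4), function(nm) {
    list(cols = cols[[nm]], dist = dist)
  })
  if (!is.null(policy_z)) {
    spatial <- c(spatial, list(list(cols = cols$a, dist = dist)))
  }
  list(X = X, y = df$y, cols = cols, spatial = spatial,
       cities = cities, city_idx = city_idx, dow = dow, Csum = Csum,
       data = df)
}

new_pollution_fit <- function(eng, frame, spec, prior, settings, pollutant) {
  structure(
    list(
      pollutant = pollutant,
      cities = frame$cities,
      spline_spec = spec,
      cols = frame$cols,
      Csum = frame$Csum,
      coef_draws = eng$coef_draws,
      coef_mean = eng$coef_mean,
      sigma_draws = eng$sigma_draws,
      theta_draws = eng$theta_draws,
      prior = prior,
      settings = settings,
      diagnostics = eng$diagnostics
    ),
    class = "pollution_fit"
  )
}

#' Fit the spatially structured stringency exposure-response model
#'
#' Models the daily pollutant change \eqn{y_{it}} (Lockdown minus
#' business-as-usual, ug/m3) as an anchored natural-spline function of the
#' Stringency Index with city-specific spline coefficients, plus
#' city-specific sum-to-zero day-of-week effects and z-scored NDVI and
#' built-up covariates, with no global intercept:
#' \deqn{y_{it} = f(x_{it}; \beta + b_i) + \gamma_{1i} DOW_t +
#'   \gamma_2 NDVI_i + \gamma_3 BuiltUp_i + \epsilon_{it}.}
#' Each of the four coordinates of the city deviations \eqn{b_i} carries an
#' independent Matern Gaussian-process prior over great-circle distances,
#' with penalized-complexity priors on its range and standard deviation.
#' Inference uses a collapsed Metropolis sampler over the hyperparameters
#' with the Gaussian coefficient layer integrated out (see
#' [engine_settings()]).
#'
#' @param panel Pollution panel (single pollutant).
#' @param si SI series aligned with the panel.
#' @param cities City table covering every panel city.
#' @param spec Optional [spline_spec()]; by default knots are placed at
#'   the 25/50/75% quantiles of the pooled observed SI.
#' @param prior A [pc_prior()] shared by all spatial fields.
#' @param settings An [engine_settings()].
#' @return A `pollution_fit` object carrying posterior draws of all
#'   coefficients and hyperparameters, plus convergence diagnostics.
#' @export
fit_pollution_model <- function(panel, si, cities, spec = NULL,
                                prior = pc_prior(), settings = engine_settings()) {
  if (is.null(spec)) {
    pooled <- si %>% filter(.data$city_id %in% unique(panel$city_id))
    spec <- spline_spec(pooled$si)
  }
  frame <- build_model_frame(panel, si, cities, spec)
  eng <- collapsed_gaussian_fit(
    frame$X, frame$y, frame$spatial, prior, settings = settings
  )
  if (!eng$diagnostics$converged) {
    warn("Sampler diagnostics flag possible non-convergence; inspect `$diagnostics`.")
  }
  new_pollution_fit(eng, frame, spec, prior, settings,
                    pollutant = unique(panel$pollutant))
}

# draws helpers ---------------------------------------------------------

beta_draws <- function(fit) fit$coef_draws[, fit$cols$beta, drop = FALSE]

b_draws <- function(fit, city_id) {
  i <- match(city_id, fit$cities$city_id)
  if (is.na(i)) abort(paste0("Unknown city: ", city_id))
  sapply(1:4, function(k) fit$coef_draws[, fit$cols[[paste0("b", k)]][i]])
}

#' Posterior day-of-week effects
#'
#' Expands the six free sum-to-zero contrasts per city back to the seven
#' daily effects; each posterior draw sums to zero within city.
#'
#' @param fit A `pollution_fit`.
#' @return Array `n_draws x n_cities x 7`.
#' @export
dow_effects <- function(fit) {
  nd <- nrow(fit$coef_draws)
  n_c <- nrow(fit$cities)
  out <- array(NA_real_, c(nd, n_c, 7))
  for (i in seq_len(n_c)) {
    free <- fit$coef_draws[, fit$cols$dow[(i - 1L) * 6L + 1:6], drop = FALSE]
    out[, i, ] <- free %*% t(fit$Csum)
  }
  out
}

#' Posterior exposure-response curve
#'
#' Predicted pollutant change across an SI grid, isolating the spline term
#' \eqn{f}: covariate and day-of-week contributions are excluded. For
#' `city_id = "average"` the curve uses the fixed coefficients only; for a
#' named city it uses the city's own coefficients (fixed + deviation).
#'
#' @param fit A `pollution_fit`.
#' @param si_grid SI values, by default 0 to 80 (levels above 80 were
#'   rarely observed).
#' @param city_id `"average"` or one `city_id`.
#' @param level Credible level, default 0.95.
#' @return A tibble `si`, `city_id`, `estimate`, `lo`, `hi`, with an
#'   `extrapolated` attribute flagging grid points beyond the fitted
#'   boundary.
#' @export
predict_curve <- function(fit, si_grid = 0:80, city_id = "average",
                          level = 0.95) {
  extrap <- si_grid < fit$spline_spec$boundary[1] - 1e-8 |
    si_grid > fit$spline_spec$boundary[2] + 1e-8
  if (any(extrap)) {
    warn("SI grid extends beyond the fitted boundary; extrapolating linearly.")
  }
  basis <- build_spline_basis(si_grid, fit$spline_spec,
                              warn_extrapolation = FALSE)
  coefs <- t(beta_draws(fit))                       # 4 x draws
  coef_pt <- fit$coef_mean[fit$cols$beta]
  if (!identical(city_id, "average")) {
    coefs <- coefs + t(b_draws(fit, city_id))
    i <- match(city_id, fit$cities$city_id)
    coef_pt <- coef_pt + vapply(
      1:4, function(k) fit$coef_mean[fit$cols[[paste0("b", k)]][i]],
      numeric(1)
    )
  }
  curves <- basis %*% coefs                         # grid x draws
  ci <- t(apply(curves, 1, empirical_ci, level = level))
  out <- tibble(
    si = si_grid, city_id = city_id,
    estimate = as.numeric(basis %*% coef_pt), lo = ci[, 1], hi = ci[, 2]
  )
  attr(out, "extrapolated") <- extrap
  out
}

#' Per-city predicted change at a fixed SI
#'
#' @param fit A `pollution_fit`.
#' @param si A single SI value (percent), e.g. 80.
#' @param level Credible level.
#' @return A tibble with one row per city: `city_id`, `estimate`, `lo`,
#'   `hi` (ug/m3).
#' @export
predict_at_si <- function(fit, si, level = 0.95) {
  stopifnot(length(si) == 1)
  basis <- build_spline_basis(si, fit$spline_spec, warn_extrapolation = FALSE)
  bd <- beta_draws(fit)
  purrr::map(fit$cities$city_id, function(cid) {
    draws <- (bd + b_draws(fit, cid)) %*% t(basis)
    i <- match(cid, fit$cities$city_id)
    coef_pt <- fit$coef_mean[fit$cols$beta] + vapply(
      1:4, function(k) fit$coef_mean[fit$cols[[paste0("b", k)]][i]],
      numeric(1)
    )
    ci <- empirical_ci(draws[, 1], level = level)
    tibble(city_id = cid, si = si,
           estimate = as.numeric(basis %*% coef_pt),
           lo = ci[1], hi = ci[2])
  }) %>% bind_rows()
}

#' @export
print.pollution_fit <- function(x, ...) {
  cat("Spatially structured stringency exposure-response fit\n")
  cat("  pollutant:   ", x$pollutant, "\n")
  cat("  cities:      ", nrow(x$cities), "\n")
  cat("  draws:       ", nrow(x$coef_draws), "\n")
  cat("  residual sd: ", signif(mean(x$sigma_draws), 3), "\n")
  cat("  acceptance:  ", signif(x$diagnostics$acceptance_rate, 3),
      if (x$diagnostics$converged) "(converged)" else "(check diagnostics!)",
      "\n")
  invisible(x)
}
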