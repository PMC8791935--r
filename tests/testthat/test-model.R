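# Fits in this file use short chains; sampler warnings about conservative
# convergence flags are expected at these chain lengths and are silenced.
fit_quiet <- function(...) suppressWarnings(fit_pollution_model(...))

test_that("noiseless data identify the exposure-response exactly", {
  cities <- generate_cities(6, seed = 101)
  policies <- generate_policy_panel(cities, seed = 102)
  si <- compute_si(policies)
  truth <- synthetic_truth(cities, matern_sd = 0, dow_sd = 0,
                           ndvi_coef = 0, builtup_coef = 0,
                           residual_sd = 0, seed = 103)
  panel <- generate_pollution_panel(cities, si, truth, "NO2")
  fit <- fit_quiet(panel, si, cities, settings = fast_engine(seed = 104))
  grid <- seq(0, 80, 5)
  pc <- predict_curve(fit, grid)
  tc <- as.numeric(
    build_spline_basis(grid, attr(panel, "spline_spec"),
                       warn_extrapolation = FALSE) %*%
      truth$fixed_spline_coefficients
  )
  expect_lt(max(abs(pc$estimate - tc)), 1e-3)
})

test_that("forcing the spatial sd to zero reduces to the non-spatial model", {
  w <- make_world(8, seed = 111, residual_sd = 1, matern_sd = 0)
  shrink <- pc_prior(range0 = 500, alpha_range = 0.5,
                     sd0 = 1e-3, alpha_sd = 0.01)
  fit <- fit_quiet(w$panel, w$si, w$cities, prior = shrink,
                   settings = fast_engine(seed = 112, n_iter = 1500,
                                          n_burn = 500))

  # independent penalized-least-squares oracle: plain lm on the same
  # design without the (shrunk-away) spatial deviations
  frame <- stringair:::build_model_frame(w$panel, w$si, w$cities,
                                         fit$spline_spec)
  keep <- c(frame$cols$beta, frame$cols$dow, frame$cols$cov)
  ls_fit <- lm.fit(frame$X[, keep], frame$y)
  beta_ls <- ls_fit$coefficients[1:4]
  beta_post <- fit$coef_mean[fit$cols$beta]
  expect_equal(unname(beta_post), unname(beta_ls), tolerance = 0.05)
})

test_that("posterior curves honour the anchoring and linearity contracts", {
  w <- make_world(8, seed = 121, residual_sd = 1)
  fit <- fit_quiet(w$panel, w$si, w$cities, settings = fast_engine(seed = 122))

  # SI = 0: zero change with zero-width band, for the average and cities
  pc0 <- predict_curve(fit, 0)
  expect_equal(pc0$estimate, 0)
  expect_equal(pc0$lo, 0)
  expect_equal(pc0$hi, 0)
  at0 <- predict_at_si(fit, 0)
  expect_equal(at0$estimate, rep(0, 8))
  expect_equal(at0$lo, rep(0, 8))

  # city curve minus average curve is the deviation-only spline term
  grid <- seq(0, 80, 10)
  cid <- w$cities$city_id[3]
  avg <- predict_curve(fit, grid, "average")
  city <- predict_curve(fit, grid, cid)
  basis <- build_spline_basis(grid, fit$spline_spec,
                              warn_extrapolation = FALSE)
  i <- match(cid, fit$cities$city_id)
  b_mean <- vapply(1:4, function(k) {
    fit$coef_mean[fit$cols[[paste0("b", k)]][i]]
  }, numeric(1))
  expect_equal(city$estimate - avg$estimate, as.numeric(basis %*% b_mean),
               tolerance = 1e-10)

  # band endpoints are the 2.5/97.5 percentiles of draw-wise curves
  curves <- basis %*% t(fit$coef_draws[, fit$cols$beta])
  manual <- t(apply(curves, 1, quantile, probs = c(0.025, 0.975), type = 7))
  expect_equal(avg$lo, unname(manual[, 1]))
  expect_equal(avg$hi, unname(manual[, 2]))

  # predict_at_si equals the city curve at the single grid point
  at80 <- predict_at_si(fit, 80)
  expect_equal(at80$estimate[i], city$estimate[city$si == 80])

  # day-of-week effects sum to zero draw-wise
  dow <- dow_effects(fit)
  expect_lt(max(abs(apply(dow, c(1, 2), sum))), 1e-10)

  # extrapolation beyond the fitted boundary warns
  expect_warning(predict_curve(fit, c(0, 150)), "boundary")
})

test_that("city ranking at SI = 80 is recovered from synthetic data", {
  w <- make_world(12, seed = 131, residual_sd = 1, matern_sd = 1.5)
  fit <- fit_quiet(w$panel, w$si, w$cities, settings = fast_engine(seed = 132))
  at80 <- predict_at_si(fit, 80)
  basis80 <- build_spline_basis(80, w$spec, warn_extrapolation = FALSE)
  truth80 <- as.numeric(
    basis80 %*% t(sweep(w$truth$city_deviations, 2,
                        w$truth$fixed_spline_coefficients, "+"))
  )
  expect_gte(cor(at80$estimate, truth80, method = "spearman"), 0.8)
})

test_that("posterior predictive mean matches the sample mean", {
  w <- make_world(8, seed = 141, residual_sd = 1)
  fit <- fit_quiet(w$panel, w$si, w$cities, settings = fast_engine(seed = 142))
  frame <- stringair:::build_model_frame(w$panel, w$si, w$cities,
                                         fit$spline_spec)
  mu <- as.numeric(frame$X %*% fit$coef_mean)
  expect_lt(abs(mean(mu) - mean(frame$y)), 0.05 * sd(frame$y))
})

test_that("interval coverage for the fixed coefficients is calibrated", {
  # reduced-size replicate experiment: 10 cities x 60 days
  covered <- 0L
  total <- 0L
  for (r in 1:20) {
    cities <- generate_cities(10, seed = 1000 + r)
    policies <- generate_policy_panel(cities, end = as.Date("2020-03-31"),
                                      seed = 2000 + r)
    si <- compute_si(policies)
    truth <- synthetic_truth(cities, residual_sd = 1, matern_sd = 0.5,
                             seed = 3000 + r)
    panel <- generate_pollution_panel(cities, si, truth, "NO2")
    fit <- fit_quiet(panel, si, cities,
                     settings = fast_engine(seed = 4000 + r, n_iter = 600,
                                            n_burn = 200, n_draws = 150))
    bd <- fit$coef_draws[, fit$cols$beta, drop = FALSE]
    for (k in 1:4) {
      ci <- quantile(bd[, k], c(0.025, 0.975), type = 7)
      covered <- covered +
        (ci[1] <= truth$fixed_spline_coefficients[k] &&
           truth$fixed_spline_coefficients[k] <= ci[2])
      total <- total + 1L
    }
  }
  coverage <- covered / total
  expect_gte(coverage, 0.80)
  expect_lte(coverage, 1.00)
})

test_that("misaligned panels are rejected with a validation error", {
  w <- make_world(4, seed = 151, end = as.Date("2020-03-31"))
  si_short <- w$si[w$si$date > as.Date("2020-02-05"), ]
  expect_error(fit_quiet(w$panel, si_short, w$cities), "Misaligned")
  two_poll <- w$panel
  two_poll$pollutant[1] <- "O3"
  expect_error(fit_quiet(two_poll, w$si, w$cities), "one pollutant|single|per call")
})
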