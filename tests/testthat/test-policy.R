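fit_policy_quiet <- function(...) suppressWarnings(fit_policy_model(...))

test_that("a known injected policy effect is recovered", {
  pw <- make_policy_world(10, alpha = -3, seed = 201,
                          end = as.Date("2020-05-31"))
  fit <- fit_policy_quiet(pw$panel, pw$policies, "C1", pw$cities,
                          settings = fast_engine(seed = 202, n_iter = 1200,
                                                 n_burn = 400))
  a <- alpha_summary(fit)
  expect_lte(abs(a$alpha_mean - pw$alpha), 0.25 * abs(pw$alpha))
  expect_gte(pw$alpha, a$lo)
  expect_lte(pw$alpha, a$hi)
  expect_lte(a$lo, a$alpha_mean)
  expect_gte(a$hi, a$alpha_mean)
})

test_that("a never-implemented policy is a degenerate design, not a zero", {
  w <- make_world(4, seed = 211, end = as.Date("2020-03-31"))
  silent <- w$policies
  silent$level[silent$indicator_id == "C5"] <- 0L
  expect_error(
    fit_policy_quiet(w$panel, silent, "C5", w$cities,
                     settings = fast_engine(seed = 212)),
    "Degenerate"
  )
})

test_that("alpha is scale-free in the indicator's number of levels", {
  # doubling max_level with the same standardized trajectory leaves z,
  # and hence the whole fit, unchanged
  pw <- make_policy_world(6, alpha = -2, seed = 221)
  doubled <- pw$policies
  sel <- doubled$indicator_id == "C1"
  doubled$level[sel] <- doubled$level[sel] * 2L
  doubled$max_level[sel] <- doubled$max_level[sel] * 2L
  z1 <- standardize_policy_variable(pw$policies, "C1")
  z2 <- standardize_policy_variable(doubled, "C1")
  expect_equal(z1$z, z2$z)
  f1 <- fit_policy_quiet(pw$panel, pw$policies, "C1", pw$cities,
                         settings = fast_engine(seed = 222))
  f2 <- fit_policy_quiet(pw$panel, doubled, "C1", pw$cities,
                         settings = fast_engine(seed = 222))
  expect_equal(alpha_summary(f1)$alpha_mean, alpha_summary(f2)$alpha_mean)
})

test_that("run_all_policies returns one reproducible row per policy", {
  w <- make_world(5, seed = 231, end = as.Date("2020-04-30"))
  st <- fast_engine(seed = 232, n_iter = 300, n_burn = 100, n_draws = 60)
  res1 <- suppressWarnings(run_all_policies(w$panel, w$policies, w$cities,
                                            settings = st))
  expect_equal(nrow(res1), 9)
  expect_equal(res1$policy_id, si_indicators()$indicator_id)
  ok <- is.na(res1$error)
  expect_true(all(res1$lo[ok] <= res1$alpha_mean[ok]))
  expect_true(all(res1$alpha_mean[ok] <= res1$hi[ok]))
  res2 <- suppressWarnings(run_all_policies(w$panel, w$policies, w$cities,
                                            settings = st))
  expect_identical(res1, res2)
})

test_that("perfect policy collinearity widens the alpha interval", {
  # lockstep scenario: all nine indicators share one on/off trajectory,
  # so z is an exact linear function of the leave-one-out SI
  cities <- generate_cities(8, seed = 241)
  dates <- seq(as.Date("2020-02-01"), as.Date("2020-05-31"), by = "day")
  ind <- si_indicators()
  lock <- tidyr::expand_grid(
    city_id = cities$city_id, date = dates,
    indicator_id = ind$indicator_id
  ) |>
    dplyr::left_join(ind[, c("indicator_id", "max_level")],
                     by = "indicator_id") |>
    dplyr::mutate(level = dplyr::if_else(
      date >= as.Date("2020-03-15") & date < as.Date("2020-05-15"),
      max_level, 0L
    ))
  truth <- synthetic_truth(cities, residual_sd = 1, matern_sd = 0.5,
                           seed = 242)
  x_lock <- si_without(lock, "C1")
  # the lockstep SI takes only two values; anchor the spline on a spread
  # reference grid instead
  spec <- spline_spec(c(0, 25, 50, 75, 100))
  panel_lock <- generate_pollution_panel(cities, compute_si(lock), truth,
                                         "NO2", spec = spec)
  zl <- standardize_policy_variable(lock, "C1")
  panel_lock$y <- panel_lock$y -
    2 * zl$z[match(paste(panel_lock$city_id, panel_lock$date),
                   paste(zl$city_id, zl$date))]

  fit_lock <- suppressWarnings(
    fit_policy_model(panel_lock, lock, "C1", cities, spec = spec,
                     settings = fast_engine(seed = 243))
  )
  pw <- make_policy_world(8, alpha = -2, seed = 241)
  fit_indep <- fit_policy_quiet(pw$panel, pw$policies, "C1", pw$cities,
                                settings = fast_engine(seed = 243))
  w_lock <- with(alpha_summary(fit_lock), hi - lo)
  w_indep <- with(alpha_summary(fit_indep), hi - lo)
  expect_gt(w_lock, w_indep)
})
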