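test_that("relative risks convert to log-linear coefficients", {
  null_risk <- rr_to_xi("X", 1, 1, 1, 10)
  expect_equal(null_risk$xi, 0)
  expect_equal(null_risk$xi_se, 0)

  k <- rr_to_xi("NO2", 1.01, 1.005, 1.015, 10)
  expect_equal(k$xi, log(1.01) / 10)
  expect_equal(k$xi_se, (log(1.015) - log(1.005)) / (2 * 1.96 * 10))

  k20 <- rr_to_xi("NO2", 1.01, 1.005, 1.015, 20)
  expect_equal(k20$xi, k$xi / 2)
  expect_equal(k20$xi_se, k$xi_se / 2)

  expect_error(rr_to_xi("X", 1.01, 1.015, 1.005, 10), "ci_lo")
})

test_that("daily burden follows the attributable-risk formula", {
  expect_equal(daily_burden(0, 0.01, 1e6, 0.001), 0)
  expect_equal(daily_burden(-5, 0.01, 1e6, 0), 0)

  d <- daily_burden(-10, 0.01, 1e6, 0.001)
  oracle <- (0.01 / 365.25) * 1e6 * (1 - exp(0.001 * 10))
  expect_equal(d, oracle)
  expect_lt(d, 0)

  # oracle equivalence on a random grid, to near machine precision
  set.seed(7)
  y <- runif(500, -30, 10)
  m <- runif(500, 0.005, 0.02)
  p <- runif(500, 1e5, 1e7)
  xi <- runif(500, -0.002, 0.004)
  expect_equal(daily_burden(y, m, p, xi),
               m / 365.25 * p * (1 - exp(-xi * y)),
               tolerance = 1e-12)

  # sign convention: for positive xi, burden carries the sign of y
  expect_true(all(sign(daily_burden(y, m, p, abs(xi) + 1e-4)) == sign(y)))

  # first-order linearization agrees within 1% when |xi y| <= 0.01
  small <- abs(xi * y) <= 0.01 & abs(xi * y) > 0
  lin <- (m / 365.25 * p * xi * y)[small]
  expect_lt(max(abs(daily_burden(y, m, p, xi)[small] / lin - 1)), 0.01)
})

test_that("city totals are additive over days and cities", {
  w <- make_world(6, seed = 301, end = as.Date("2020-05-31"))
  coeff <- default_risks()[1, ]
  res <- total_burden(w$panel, w$cities, coeff)

  # all-zero panel
  zero <- w$panel
  zero$y <- 0
  res0 <- total_burden(zero, w$cities, coeff)
  expect_equal(res0$grand_total$total, 0)
  expect_equal(res0$city_totals$total, rep(0, 6))

  # one city, constant y: total = n_days * daily value
  one <- w$panel[w$panel$city_id == w$cities$city_id[1], ]
  one$y <- -4
  r1 <- total_burden(one, w$cities, coeff)
  expect_equal(
    r1$grand_total$total,
    nrow(one) * daily_burden(-4, w$cities$crude_death_rate[1],
                             w$cities$population[1], coeff$xi)
  )

  # splitting a panel into two date halves and summing reproduces the total
  cut <- stats::median(w$panel$date)
  ra <- total_burden(w$panel[w$panel$date <= cut, ], w$cities, coeff)
  rb <- total_burden(w$panel[w$panel$date > cut, ], w$cities, coeff)
  expect_equal(ra$grand_total$total + rb$grand_total$total,
               res$grand_total$total)
  expect_equal(sum(res$city_totals$total), res$grand_total$total)

  # a city without a death rate is a hard error
  cities_na <- w$cities
  cities_na$crude_death_rate[2] <- NA
  expect_error(total_burden(w$panel, cities_na, coeff), "unavailable")
})

test_that("Monte-Carlo intervals behave and reproduce exactly", {
  w <- make_world(5, seed = 311, end = as.Date("2020-05-31"))
  coeff <- default_risks()[1, ]

  # xi_se = 0 collapses intervals onto the point estimate exactly
  degenerate <- coeff
  degenerate$xi_se <- 0
  r0 <- mc_uncertainty(w$panel, w$cities, degenerate, n_mc = 100, seed = 1)
  expect_identical(r0$city_totals$lo, r0$city_totals$total)
  expect_identical(r0$city_totals$hi, r0$city_totals$total)
  expect_identical(r0$grand_total$lo, r0$grand_total$total)

  # intervals contain the point estimate (monotone map of xi), across seeds
  for (s in 1:5) {
    r <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 200, seed = s)
    expect_true(all(r$city_totals$lo <= r$city_totals$total + 1e-12))
    expect_true(all(r$city_totals$hi >= r$city_totals$total - 1e-12))
  }

  # identical seed, identical intervals, bit for bit
  ra <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 500, seed = 42)
  rb <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 500, seed = 42)
  expect_identical(ra$city_totals, rb$city_totals)

  # doubling n_mc moves the endpoints by less than ~3 MC standard errors
  # of the 2.5th percentile; the grand total is monotone in xi, so the
  # percentile SE transfers through the (near-linear) map xi -> total
  r1 <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 1000, seed = 9)
  r2 <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 2000, seed = 9)
  q025 <- stats::qnorm(0.025, coeff$xi, coeff$xi_se)
  se_q_xi <- sqrt(0.025 * 0.975 / 1000) /
    stats::dnorm(q025, coeff$xi, coeff$xi_se)
  slope <- abs(r1$grand_total$total / coeff$xi)
  expect_lt(abs(r1$grand_total$lo - r2$grand_total$lo),
            3 * se_q_xi * slope)
})

test_that("reports aggregate cities with a TOTAL row", {
  w <- make_world(5, seed = 321, end = as.Date("2020-05-31"))
  coeff <- default_risks()[1, ]
  b <- mc_uncertainty(w$panel, w$cities, coeff, n_mc = 200, seed = 2)
  rep <- make_report(list(b), w$cities, w$si)
  expect_equal(nrow(rep), 6)
  tot <- rep[rep$city == "TOTAL", ]
  expect_equal(tot$population, sum(rep$population[rep$city != "TOTAL"]))
  expect_equal(tot$NO2, sum(rep$NO2[rep$city != "TOTAL"]))

  # single-city report: TOTAL equals the city row
  one_city <- w$cities[1, ]
  one_panel <- w$panel[w$panel$city_id == one_city$city_id, ]
  b1 <- mc_uncertainty(one_panel, one_city, coeff, n_mc = 100, seed = 3)
  rep1 <- make_report(list(b1), one_city)
  expect_equal(rep1$NO2[1], rep1$NO2[2])
  expect_equal(rep1$population[1], rep1$population[2])

  # inconsistent city sets across pollutants are rejected
  b_sub <- mc_uncertainty(w$panel[w$panel$city_id != w$cities$city_id[1], ],
                          w$cities, coeff, n_mc = 100, seed = 4)
  b_sub$pollutant <- "O3"
  expect_error(make_report(list(b, b_sub), w$cities), "Inconsistent")
})

test_that("the published city table is intact", {
  pub <- published_city_table()
  expect_equal(nrow(pub), 47)
  expect_true(all(is.na(pub[pub$city == "Pristina",
                            c("no2", "o3", "pm25", "pm10")])))
  expect_equal(sum(!is.na(pub$no2)), 46)
})
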