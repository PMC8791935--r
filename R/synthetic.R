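#' Ground truth for the synthetic pollutant-change generator
#'
#' Collects every parameter of the generative model in one record: the
#' four fixed natural-spline coefficients (shared exposure-response), the
#' spatially correlated city deviations from them, city-specific
#' day-of-week effects constrained to sum to zero (required for
#' identifiability since the model carries no intercept), scalar
#' coefficients for the z-scored NDVI and built-up covariates, the
#' residual standard deviation, and the Matern hyperparameters of the
#' spatial fields.
#'
#' @param cities A city table from [generate_cities()].
#' @param fixed_spline_coefficients 4-vector of spline coefficients
#'   (ug/m3 per basis unit). The default gives a smooth negative
#'   exposure-response reaching roughly -8 ug/m3 at high stringency,
#'   comparable to the NO2 declines seen in large European cities.
#' @param matern_range_km,matern_sd,nu Matern parameters of the spatial
#'   field behind the city deviations.
#' @param dow_sd Standard deviation of the (centred) day-of-week effects.
#' @param ndvi_coef,builtup_coef Coefficients on the z-scored covariates.
#' @param residual_sd Standard deviation of the unstructured Gaussian
#'   residual, ug/m3.
#' @param seed Integer seed governing every random draw in the truth and
#'   in panels generated from it.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(cities,
                            fixed_spline_coefficients = c(-2, -4.5, -9, -6.5),
                            matern_range_km = 600, matern_sd = 1, nu = 1,
                            dow_sd = 0.3,
                            ndvi_coef = 0.5, builtup_coef = -0.5,
                            residual_sd = 2,
                            seed = 1) {
  validate_cities(cities)
  stopifnot(
    length(fixed_spline_coefficients) == 4,
    residual_sd >= 0, matern_range_km > 0, matern_sd >= 0
  )
  n <- nrow(cities)
  b <- sample_city_deviations(
    cities, matern_range_km, matern_sd, nu = nu, n_fields = 4, seed = seed
  )
  dow <- with_seed(seed + 1L, matrix(rnorm(n * 7, sd = dow_sd), n, 7))
  dow <- dow - rowMeans(dow)
  structure(
    list(
      fixed_spline_coefficients = as.numeric(fixed_spline_coefficients),
      city_deviations = b,
      dow_effects = dow,
      ndvi_coef = ndvi_coef, builtup_coef = builtup_coef,
      residual_sd = residual_sd,
      matern_range_km = matern_range_km, matern_sd = matern_sd, nu = nu,
      city_id = cities$city_id,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' Generate a synthetic national policy-response panel
#'
#' Mimics the first-wave trajectory of European government responses: all
#' nine indicators at level 0 through February, a country-specific onset
#' in early-to-mid March with a stepwise jump to at-or-near-maximum
#' levels (so the resulting Stringency Index plateaus around 75-90), a
#' plateau, and stepwise relaxation starting between mid-May and early
#' June. All cities of a country share one series; every indicator series
#' is piecewise constant with few change-points.
#'
#' @param cities A city table.
#' @param start_date,end_date `Date` range, `start_date < end_date`.
#' @param seed Integer seed.
#' @return A policy-panel tibble (long format, validated).
#' @export
generate_policy_panel <- function(cities,
                                  start_date = as.Date("2020-02-01"),
                                  end_date = as.Date("2020-07-31"),
                                  seed = 1) {
  if (nrow(cities) == 0) abort("Empty city list.")
  validate_cities(cities)
  if (!inherits(start_date, "Date")) start_date <- as.Date(start_date)
  if (!inherits(end_date, "Date")) end_date <- as.Date(end_date)
  if (start_date >= end_date) abort("`start_date` must precede `end_date`.")
  dates <- seq(start_date, end_date, by = "day")
  ind <- si_indicators()
  countries <- unique(cities$country)

  country_series <- with_seed(seed, {
    purrr::map(setNames(countries, countries), function(ctry) {
      onset <- as.Date("2020-03-05") + sample.int(14, 1) - 1
      relax <- as.Date("2020-05-10") + sample.int(28, 1) - 1
      purrr::map2(ind$indicator_id, ind$max_level, function(id, mx) {
        i_onset <- onset + sample.int(5, 1) - 1
        plateau <- if (runif(1) < 0.6) mx else sample.int(mx, 1)
        lev <- integer(length(dates))
        ramp <- runif(1) < 0.5 && plateau > 1
        if (ramp) {
          mid <- ceiling(plateau / 2)
          mid_days <- sample(3:7, 1)
          lev[dates >= i_onset] <- mid
          lev[dates >= i_onset + mid_days] <- plateau
        } else {
          lev[dates >= i_onset] <- plateau
        }
        # stepwise relaxation: one level down every 2-4 weeks
        gap <- sample(14:28, 1)
        floor_lev <- sample(0:1, 1)
        k <- 1
        while (plateau - k >= floor_lev) {
          lev[dates >= relax + (k - 1) * gap] <- plateau - k
          k <- k + 1
        }
        tibble(date = dates, indicator_id = id, level = lev, max_level = mx)
      }) %>% bind_rows()
    })
  })

  purrr::map2(cities$city_id, cities$country, function(cid, ctry) {
    mutate(country_series[[ctry]], city_id = cid, .before = 1)
  }) %>%
    bind_rows() %>%
    arrange(.data$city_id, .data$date, .data$indicator_id)
}

#' Generate a synthetic pollutant-difference panel
#'
#' Simulates the daily Lockdown-minus-BAU pollutant change for every
#' city-day from the same additive structure the estimation model
#' assumes: an anchored natural-spline function of the Stringency Index
#' with city-specific spline coefficients (fixed effect + spatially
#' correlated deviation), city-specific sum-to-zero day-of-week effects,
#' z-scored NDVI and built-up covariate terms, and i.i.d. Gaussian noise.
#'
#' @param cities A city table.
#' @param si An SI series tibble (`city_id`, `date`, `si`) covering all
#'   city-days, e.g. from [compute_si()].
#' @param truth A [synthetic_truth()] whose `city_deviations` rows match
#'   `cities`.
#' @param pollutant Pollutant label attached to the panel
#'   (`"NO2"`, `"O3"`, `"PM25"`, `"PM10"`).
#' @param spec Optional [spline_spec()]; by default derived from the
#'   pooled SI values, exactly as the estimation model derives it.
#' @return A pollution-panel tibble (`city_id`, `date`, `pollutant`, `y`)
#'   with the [spline_spec()] used attached as attribute `"spline_spec"`.
#' @export
generate_pollution_panel <- function(cities, si, truth, pollutant = "NO2",
                                     spec = NULL) {
  validate_cities(cities)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nrow(truth$city_deviations) != nrow(cities)) {
    abort("`truth$city_deviations` row count must equal the number of cities.")
  }
  if (any(si$si < 0 | si$si > 100)) abort("SI values must lie in [0, 100].")
  missing_cities <- setdiff(cities$city_id, si$city_id)
  if (length(missing_cities) > 0) {
    abort(paste0("SI series missing city: ", missing_cities[1]))
  }

  if (is.null(spec)) spec <- spline_spec(si$si)
  df <- si %>%
    filter(.data$city_id %in% cities$city_id) %>%
    arrange(.data$city_id, .data$date) %>%
    left_join(
      cities %>% select("city_id", "ndvi", "builtup"),
      by = "city_id"
    ) %>%
    mutate(
      city_idx = match(.data$city_id, cities$city_id),
      dow = as.POSIXlt(.data$date)$wday + 1L
    )
  # covariates are z-scored across cities, not across city-days
  df$ndvi_z <- as.numeric(scale(cities$ndvi))[df$city_idx]
  df$builtup_z <- as.numeric(scale(cities$builtup))[df$city_idx]

  basis <- build_spline_basis(df$si, spec)
  coef_by_city <- sweep(truth$city_deviations, 2,
                        truth$fixed_spline_coefficients, "+")
  f <- rowSums(basis * coef_by_city[df$city_idx, , drop = FALSE])
  dow_term <- truth$dow_effects[cbind(df$city_idx, df$dow)]
  mu <- f + dow_term +
    truth$ndvi_coef * df$ndvi_z + truth$builtup_coef * df$builtup_z
  eps <- if (truth$residual_sd > 0) {
    with_seed(truth$seed + 2L, rnorm(nrow(df), sd = truth$residual_sd))
  } else {
    0
  }
  out <- tibble(
    city_id = df$city_id, date = df$date,
    pollutant = pollutant, y = mu + eps
  )
  attr(out, "spline_spec") <- spec
  out
}

validate_pollution_panel <- function(panel, call = rlang::caller_env()) {
  required <- c("city_id", "date", "pollutant", "y")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("Pollution panel missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  if (any(!is.finite(panel$y))) abort("Non-finite y values.", call = call)
  dup <- panel %>%
    count(.data$city_id, .data$date, .data$pollutant) %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate (city, date, pollutant) rows, e.g. ",
                 dup$city_id[1], " ", dup$date[1]), call = call)
  }
  invisible(panel)
}

#' Read or write a pollutant-difference panel
#'
#' @param path CSV path with columns `city_id`, `date`, `pollutant`, `y`.
#' @return `read_pollution_panel()`: a validated tibble.
#' @export
read_pollution_panel <- function(path) {
  panel <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)) %>%
    mutate(date = as.Date(.data$date))
  validate_pollution_panel(panel)
  panel
}

#' @rdname read_pollution_panel
#' @param panel A pollution panel.
#' @export
write_pollution_panel <- function(panel, path) {
  validate_pollution_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / recover a synthetic ground truth
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- truth
  x$city_deviations <- as.data.frame(x$city_deviations)
  x$dow_effects <- as.data.frame(x$dow_effects)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$city_deviations <- unname(as.matrix(x$city_deviations))
  x$dow_effects <- unname(as.matrix(x$dow_effects))
  x$fixed_spline_coefficients <- as.numeric(x$fixed_spline_coefficients)
  x$seed <- as.integer(x$seed)
  structure(x, class = "synthetic_truth")
}
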