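# Shared fixture builder: a small synthetic world (cities, policy panel,
# SI series, ground truth, pollutant panel), cached per configuration so
# test files can reuse it without regenerating.
.world_cache <- new.env(parent = emptyenv())

make_world <- function(n_cities = 8, seed = 1,
                       start = as.Date("2020-02-01"),
                       end = as.Date("2020-07-31"),
                       residual_sd = 1, matern_sd = 1, ...) {
  key <- paste(n_cities, seed, start, end, residual_sd, matern_sd,
               paste(unlist(list(...)), collapse = "_"), sep = "|")
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cities <- generate_cities(n_cities, seed = seed)
  policies <- generate_policy_panel(cities, start, end, seed = seed + 1)
  si <- compute_si(policies)
  truth <- synthetic_truth(cities, seed = seed + 2,
                           residual_sd = residual_sd,
                           matern_sd = matern_sd, ...)
  panel <- generate_pollution_panel(cities, si, truth, "NO2")
  w <- list(cities = cities, policies = policies, si = si,
            truth = truth, panel = panel,
            spec = attr(panel, "spline_spec"))
  .world_cache[[key]] <- w
  w
}

fast_engine <- function(seed = 1, n_iter = 800, n_burn = 300, n_draws = 200) {
  engine_settings(n_iter = n_iter, n_burn = n_burn, n_draws = n_draws,
                  seed = seed)
}

# true fixed-effect curve on a grid, using the same anchored basis the
# generator used
truth_curve <- function(world, grid) {
  b <- build_spline_basis(grid, world$spec, warn_extrapolation = FALSE)
  as.numeric(b %*% world$truth$fixed_spline_coefficients)
}

# independent haversine implementation (plain spherical law of haversines),
# used as the distance oracle
haversine_oracle <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a))) / 1000
}

# inject a known policy effect on top of the leave-one-out structure:
# y = (alpha + a_i) z + f(x'; beta + b_i) + dow + covariates + noise
make_policy_world <- function(n_cities, alpha, policy_id = "C1", seed = 1,
                              end = as.Date("2020-04-30"),
                              residual_sd = 1) {
  cities <- generate_cities(n_cities, seed = seed)
  policies <- generate_policy_panel(cities, end = end, seed = seed + 1)
  x_prime <- si_without(policies, policy_id)
  truth <- synthetic_truth(cities, residual_sd = residual_sd,
                           matern_sd = 0.5, seed = seed + 2)
  base <- generate_pollution_panel(cities, x_prime, truth, "NO2")
  z <- standardize_policy_variable(policies, policy_id)
  a_i <- sample_city_deviations(cities, 600, 0.3, n_fields = 1,
                                seed = seed + 3)[, 1]
  panel <- dplyr::left_join(base, z, by = c("city_id", "date"))
  panel$y <- panel$y +
    (alpha + a_i[match(panel$city_id, cities$city_id)]) * panel$z
  panel$z <- NULL
  attr(panel, "spline_spec") <- attr(base, "spline_spec")
  list(cities = cities, policies = policies, panel = panel,
       truth = truth, alpha = alpha, policy_id = policy_id)
}

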