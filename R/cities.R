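#' Generate synthetic city metadata
#'
#' Emulates the static per-city record used throughout the pipeline:
#' coordinates inside a Europe-like bounding box (lon -10..30, lat 35..65),
#' population log-uniform between 1e5 and 1e7, annual crude all-cause
#' death rate uniform in 0.008-0.012 per person-year, plus greenness
#' (NDVI) and built-up-area covariates. Cities are grouped into countries
#' because policy responses are national.
#'
#' @param n Number of cities (>= 2; spatial covariance is undefined for a
#'   single site).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with columns `city_id`, `name`, `country`, `lon`,
#'   `lat`, `population`, `ndvi`, `builtup`, `crude_death_rate`.
#' @export
#' @examples
#' generate_cities(5, seed = 1)
generate_cities <- function(n, seed = 1) {
  if (n < 2) abort("Need at least 2 cities (spatial covariance undefined).")
  with_seed(seed, {
    n_countries <- max(2L, round(0.8 * n))
    country_idx <- sort(sample.int(n_countries, n, replace = TRUE))
    tibble(
      city_id = sprintf("city_%02d", seq_len(n)),
      name = sprintf("City %02d", seq_len(n)),
      country = sprintf("country_%02d", country_idx),
      lon = runif(n, -10, 30),
      lat = runif(n, 35, 65),
      population = 10^runif(n, 5, 7),
      ndvi = runif(n, 0.2, 0.7),
      builtup = runif(n, 0.1, 0.6),
      crude_death_rate = runif(n, 0.008, 0.012)
    )
  })
}

validate_cities <- function(cities, call = rlang::caller_env()) {
  required <- c("city_id", "country", "lon", "lat", "population",
                "ndvi", "builtup", "crude_death_rate")
  missing_cols <- setdiff(required, names(cities))
  if (length(missing_cols) > 0) {
    abort(paste0("City table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  with(cities, {
    if (any(population <= 0)) abort("Populations must be positive.", call = call)
    ok_rate <- is.na(crude_death_rate) |
      (crude_death_rate > 0 & crude_death_rate < 0.05)
    if (any(!ok_rate)) {
      abort("Crude death rates must lie in (0, 0.05) per person-year.",
            call = call)
    }
    if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
      abort("Coordinates out of range.", call = call)
    }
  })
  if (anyDuplicated(cities$city_id)) abort("Duplicate city_id.", call = call)
  invisible(cities)
}

#' Read or write a city metadata table
#'
#' @param path CSV path.
#' @return `read_cities()`: a validated city tibble.
#' @export
read_cities <- function(path) {
  cities <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_cities(cities)
  cities
}

#' @rdname read_cities
#' @param cities A city table.
#' @export
write_cities <- function(cities, path) {
  validate_cities(cities)
  utils::write.csv(cities, path, row.names = FALSE)
  invisible(path)
}
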