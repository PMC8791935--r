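#' City-by-pollutant mortality report
#'
#' Assembles the per-city burden totals of one or more pollutants into a
#' single wide table: one row per city with population and maximum daily
#' SI, a `total (lo; hi)` cell per pollutant, and a closing TOTAL row
#' whose cells are column sums over the cities. Cities lacking mortality
#' data appear as NA and are excluded from the TOTAL row.
#'
#' @param burdens Named list of `burden_result` objects (one per
#'   pollutant), all computed on the same city set.
#' @param cities City table (may include cities with `NA` crude death
#'   rate, which the burdens necessarily exclude).
#' @param si Optional SI series used to fill the `max_si` column.
#' @return A tibble: `city`, `country`, `population`, `max_si`, then
#'   `<pollutant>`, `<pollutant>_lo`, `<pollutant>_hi` per pollutant; last
#'   row is `TOTAL`.
#' @export
make_report <- function(burdens, cities, si = NULL) {
  if (inherits(burdens, "burden_result")) burdens <- list(burdens)
  stopifnot(length(burdens) >= 1)
  names(burdens) <- purrr::map_chr(burdens, "pollutant")
  sets <- purrr::map(burdens, ~ sort(.x$city_totals$city_id))
  if (length(unique(sets)) != 1) {
    abort("Inconsistent city sets across pollutants.")
  }
  base <- cities %>%
    select("city_id", city = "name", "country", "population") %>%
    mutate(max_si = NA_real_)
  if (!"name" %in% names(cities)) base$city <- cities$city_id
  if (!is.null(si)) {
    mx <- si %>%
      group_by(.data$city_id) %>%
      summarise(max_si = max(.data$si), .groups = "drop")
    base$max_si <- mx$max_si[match(base$city_id, mx$city_id)]
  }
  for (p in names(burdens)) {
    ct <- burdens[[p]]$city_totals
    i <- match(base$city_id, ct$city_id)
    base[[p]] <- ct$total[i]
    base[[paste0(p, "_lo")]] <- ct$lo[i]
    base[[paste0(p, "_hi")]] <- ct$hi[i]
  }
  base <- base %>% select(-"city_id") %>% arrange(.data$city)
  total_row <- tibble(
    city = "TOTAL", country = "", population = sum(base$population),
    max_si = if (all(is.na(base$max_si))) NA_real_ else max(base$max_si, na.rm = TRUE)
  )
  for (p in names(burdens)) {
    total_row[[p]] <- sum(base[[p]], na.rm = TRUE)
    total_row[[paste0(p, "_lo")]] <- sum(base[[paste0(p, "_lo")]], na.rm = TRUE)
    total_row[[paste0(p, "_hi")]] <- sum(base[[paste0(p, "_hi")]], na.rm = TRUE)
  }
  bind_rows(base, total_row)
}

#' Published city-level burden estimates
#'
#' The published city table of the European lockdown air-quality analysis:
#' 47 cities with population, maximum daily Stringency Index, and the
#' central estimate and 95% credible limits of lockdown-attributable
#' deaths for NO2, O3, PM2.5 and PM10 (Pristina has no mortality data and
#' carries NA burdens). Used to check the report aggregation arithmetic
#' against the published grand totals.
#'
#' @return A tibble with one row per city.
#' @export
published_city_table <- function() {
  path <- system.file("extdata", "published_city_burdens.csv",
                      package = "stringair", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE))
}
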