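#' Convert a published relative risk to a log-linear mortality coefficient
#'
#' Literature relative risks are reported for a reference concentration
#' increment (typically 10 ug/m3). The per-ug/m3 log-relative-risk is
#' `xi = log(rr) / increment`, and its standard error is recovered from
#' the reported confidence interval as
#' `xi_se = (log(ci_hi) - log(ci_lo)) / (2 * 1.96 * increment)`.
#'
#' @param pollutant Pollutant identifier.
#' @param rr Published relative risk for the increment.
#' @param ci_lo,ci_hi Published 95% confidence limits, `ci_lo <= rr <= ci_hi`.
#' @param increment Concentration increment (ug/m3) the RR refers to.
#' @return A one-row tibble of class `mortality_coefficient`: `pollutant`,
#'   `xi`, `xi_se`, `source_rr`, `source_ci_lo`, `source_ci_hi`,
#'   `source_increment`.
#' @export
#' @examples
#' rr_to_xi("NO2", rr = 1.0072, ci_lo = 1.0059, ci_hi = 1.0086)
rr_to_xi <- function(pollutant, rr, ci_lo, ci_hi, increment = 10) {
  if (!(ci_lo > 0 && ci_lo <= rr && rr <= ci_hi)) {
    abort("Require 0 < ci_lo <= rr <= ci_hi.")
  }
  if (increment <= 0) abort("`increment` must be positive.")
  out <- tibble(
    pollutant = pollutant,
    xi = log(rr) / increment,
    xi_se = (log(ci_hi) - log(ci_lo)) / (2 * 1.96 * increment),
    source_rr = rr, source_ci_lo = ci_lo, source_ci_hi = ci_hi,
    source_increment = increment
  )
  class(out) <- c("mortality_coefficient", class(out))
  out
}

#' Placeholder mortality risk coefficients
#'
#' Short-term all-cause mortality relative risks per 10 ug/m3 in the range
#' reported by multi-country time-series studies. These defaults are
#' PLACEHOLDERS for pipeline demonstration: any substantive analysis must
#' supply risk values chosen from the literature via [rr_to_xi()].
#'
#' @return A `mortality_coefficient` tibble with one row per pollutant.
#' @export
default_risks <- function() {
  bind_rows(
    rr_to_xi("NO2", 1.0072, 1.0059, 1.0086, 10),
    rr_to_xi("O3", 1.0043, 1.0034, 1.0052, 10),
    rr_to_xi("PM25", 1.0065, 1.0044, 1.0086, 10),
    rr_to_xi("PM10", 1.0041, 1.0034, 1.0049, 10)
  )
}

#' Daily attributable deaths from a pollutant change
#'
#' Implements the attributable-burden formula
#' \deqn{d_{it} = m_i \, p_i \, (1 - e^{-\xi y_{it}}),}
#' where `m` is the city's crude all-cause death rate, `p` its population
#' and `y` the pollutant change (ug/m3). The crude rate is stored on the
#' annual scale and converted here to daily baseline deaths via
#' `m_annual / 365.25`; this convention rescales every burden in the
#' package and is therefore fixed in one place. Negative values are
#' avoided deaths.
#'
#' @param y Pollutant change, ug/m3 (vectorized).
#' @param m_annual Annual crude death rate, deaths per person-year.
#' @param p Population.
#' @param xi Per-ug/m3 log-relative-risk.
#' @return Deaths per day, same length as `y`.
#' @export
daily_burden <- function(y, m_annual, p, xi) {
  (m_annual / 365.25) * p * (1 - exp(-xi * y))
}

#' City and overall attributable-mortality totals
#'
#' Applies [daily_burden()] to the observed pollutant differences of every
#' city-day (independently of any fitted SI model), then sums within city
#' and overall.
#'
#' @param panel Pollution panel (single pollutant), restricted to the
#'   study window.
#' @param cities City table with `population` and `crude_death_rate` for
#'   every panel city.
#' @param coeff A one-row [rr_to_xi()] table for the panel's pollutant.
#' @return A list of class `burden_result`: `pollutant`, `daily`
#'   (city-day tibble), `city_totals`, `grand_total` (tibbles; intervals
#'   NA until [mc_uncertainty()] is used).
#' @export
total_burden <- function(panel, cities, coeff) {
  validate_pollution_panel(panel)
  validate_cities(cities)
  stopifnot(inherits(coeff, "mortality_coefficient"), nrow(coeff) == 1)
  if (length(unique(panel$pollutant)) != 1) {
    abort("One pollutant per burden computation.")
  }
  meta <- cities %>% filter(.data$city_id %in% unique(panel$city_id))
  missing_meta <- setdiff(unique(panel$city_id), meta$city_id)
  if (length(missing_meta) > 0) {
    abort(paste0("No city metadata for: ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (any(is.na(meta$crude_death_rate))) {
    abort(paste0(
      "Crude death rate unavailable for: ",
      paste(meta$city_id[is.na(meta$crude_death_rate)], collapse = ", "),
      "; exclude these cities before computing burdens."
    ))
  }
  daily <- panel %>%
    left_join(meta %>% select("city_id", "population", "crude_death_rate"),
              by = "city_id") %>%
    mutate(d = daily_burden(.data$y, .data$crude_death_rate,
                            .data$population, coeff$xi)) %>%
    select("city_id", "date", "d")
  # rowsum keeps the summation order identical to the Monte-Carlo path,
  # so degenerate (xi_se = 0) intervals collapse onto these totals exactly
  ids <- sort(unique(daily$city_id))
  city_totals <- tibble(
    city_id = ids,
    total = as.numeric(rowsum(daily$d, match(daily$city_id, ids),
                              reorder = TRUE)),
    lo = NA_real_, hi = NA_real_
  )
  grand_total <- tibble(
    total = sum(city_totals$total), lo = NA_real_, hi = NA_real_
  )
  structure(
    list(pollutant = unique(panel$pollutant), daily = daily,
         city_totals = city_totals, grand_total = grand_total,
         n_mc = NA_integer_, seed = NA_integer_),
    class = "burden_result"
  )
}

#' Monte-Carlo uncertainty for mortality burdens
#'
#' Parametric Monte-Carlo propagation of the risk-coefficient uncertainty:
#' draws `n_mc` values from Normal(`xi`, `xi_se^2`), recomputes every city
#' total per draw (one shared draw per iteration across cities, which
#' induces the correlated city intervals the totals inherit), and reports
#' empirical 2.5th/97.5th percentiles. The point estimate remains the one
#' computed at the central `xi`.
#'
#' @inheritParams total_burden
#' @param n_mc Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed (required; identical seeds reproduce intervals
#'   bit-identically).
#' @param level Credible level, default 0.95.
#' @return A `burden_result` with `lo`/`hi` filled in.
#' @export
mc_uncertainty <- function(panel, cities, coeff, n_mc = 1000, seed = 1,
                           level = 0.95) {
  if (n_mc < 2) abort("`n_mc` must be at least 2.")
  res <- total_burden(panel, cities, coeff)
  meta <- cities %>% filter(.data$city_id %in% unique(panel$city_id))
  dat <- panel %>%
    left_join(meta %>% select("city_id", "population", "crude_death_rate"),
              by = "city_id")
  xis <- with_seed(seed, rnorm(n_mc, mean = coeff$xi, sd = coeff$xi_se))
  ids <- res$city_totals$city_id
  city_idx <- match(dat$city_id, ids)
  totals <- vapply(xis, function(x) {
    d <- daily_burden(dat$y, dat$crude_death_rate, dat$population, x)
    as.numeric(rowsum(d, city_idx, reorder = TRUE))
  }, numeric(length(ids)))
  totals <- matrix(totals, nrow = length(ids))   # cities x n_mc
  ci <- t(apply(totals, 1, empirical_ci, level = level))
  res$city_totals$lo <- ci[, 1]
  res$city_totals$hi <- ci[, 2]
  grand <- colSums(totals)
  gci <- empirical_ci(grand, level = level)
  res$grand_total$lo <- gci[1]
  res$grand_total$hi <- gci[2]
  res$n_mc <- as.integer(n_mc)
  res$seed <- as.integer(seed)
  res
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Attributable-mortality burden (", x$pollutant, ")\n", sep = "")
  cat("  cities:", nrow(x$city_totals), " city-days:", nrow(x$daily), "\n")
  g <- x$grand_total
  cat("  total:", signif(g$total, 4))
  if (!is.na(g$lo)) {
    cat(" (", signif(g$lo, 4), "; ", signif(g$hi, 4), "), n_mc = ",
        x$n_mc, sep = "")
  }
  cat("\n")
  invisible(x)
}
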