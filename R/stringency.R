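#' The nine policy indicators composing the Stringency Index
#'
#' The Stringency Index (SI) summarises nine government-response indicators:
#' the eight containment-and-closure measures C1-C8 plus H1 (public
#' information campaigns). Each indicator is an ordinal level from 0 (no
#' measure) up to an indicator-specific maximum.
#'
#' @return A tibble with columns `indicator_id`, `max_level`, `label`.
#' @export
#' @examples
#' si_indicators()
si_indicators <- function() {
  tibble(
    indicator_id = c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8", "H1"),
    max_level = c(3L, 3L, 2L, 4L, 2L, 3L, 2L, 4L, 2L),
    label = c(
      "school closing", "workplace closing", "cancel public events",
      "restrictions on gatherings", "close public transport",
      "stay at home requirements", "restrictions on internal movement",
      "international travel controls", "public information campaigns"
    )
  )
}

#' Standardize a policy-indicator level to the unit interval
#'
#' Divides the ordinal level by the indicator's maximum so every measure
#' contributes on a common 0-1 scale regardless of how many levels it has.
#'
#' @param level Integer level(s), `0 <= level <= max_level`.
#' @param max_level Positive integer maximum level(s).
#' @return Numeric in `[0, 1]`, vectorized over inputs.
#' @export
#' @examples
#' standardize_indicator(2, 4)
standardize_indicator <- function(level, max_level) {
  if (any(max_level < 1)) abort("`max_level` must be >= 1.")
  if (any(level < 0)) abort("`level` must be non-negative.")
  if (any(level > max_level)) {
    abort("`level` exceeds `max_level` for at least one indicator.")
  }
  level / max_level
}

validate_policy_panel <- function(panel, call = rlang::caller_env()) {
  required <- c("city_id", "date", "indicator_id", "level", "max_level")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Policy panel is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), call = call)
  }
  if (nrow(panel) == 0) abort("Policy panel is empty.", call = call)
  bad <- which(panel$level < 0 | panel$level > panel$max_level)
  if (length(bad) > 0) {
    abort(paste0(
      "Indicator level outside [0, max_level] at row(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ), call = call)
  }
  dup <- panel %>%
    count(.data$city_id, .data$date, .data$indicator_id) %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (city, date, indicator) rows, e.g. ",
      dup$city_id[1], " ", dup$date[1], " ", dup$indicator_id[1]
    ), call = call)
  }
  gaps <- panel %>%
    count(.data$city_id, .data$date) %>%
    filter(n != 9L)
  if (nrow(gaps) > 0) {
    abort(paste0(
      "All 9 indicators (C1-C8, H1) must be present for every (city, date); ",
      "first gap: ", gaps$city_id[1], " on ", gaps$date[1],
      " has ", gaps$n[1], " indicators"
    ), call = call)
  }
  invisible(panel)
}

#' Compute the Stringency Index from a policy panel
#'
#' The SI is 100 times the mean of the nine standardized indicators, so it
#' runs from 0 (no response) to 100 (maximum response on every measure) and
#' each policy contributes equally regardless of its number of levels.
#'
#' @param panel A policy panel: one row per (city, date, indicator) with
#'   columns `city_id`, `date`, `indicator_id`, `level`, `max_level`; all
#'   nine indicators present for every city-day.
#' @return A tibble with columns `city_id`, `date`, `si` (percent, 0-100).
#' @export
#' @examples
#' cities <- generate_cities(3, seed = 1)
#' panel <- generate_policy_panel(cities,
#'   start_date = as.Date("2020-02-01"),
#'   end_date = as.Date("2020-02-10"), seed = 1)
#' compute_si(panel)
compute_si <- function(panel) {
  validate_policy_panel(panel)
  panel %>%
    mutate(std = standardize_indicator(.data$level, .data$max_level)) %>%
    group_by(.data$city_id, .data$date) %>%
    summarise(si = 100 * mean(.data$std), .groups = "drop") %>%
    arrange(.data$city_id, .data$date)
}

#' Leave-one-out Stringency Index
#'
#' Recomputes the SI as 100 times the mean of the eight remaining
#' standardized indicators after removing one policy, used when that policy
#' is modelled explicitly as its own term.
#'
#' @inheritParams compute_si
#' @param excluded One of `"C1"`..`"C8"`, `"H1"`.
#' @return A tibble with columns `city_id`, `date`, `si`.
#' @export
si_without <- function(panel, excluded) {
  ids <- si_indicators()$indicator_id
  if (length(excluded) != 1 || !excluded %in% ids) {
    abort(paste0(
      "`excluded` must be one of ", paste(ids, collapse = ", ")
    ))
  }
  validate_policy_panel(panel)
  panel %>%
    filter(.data$indicator_id != excluded) %>%
    mutate(std = standardize_indicator(.data$level, .data$max_level)) %>%
    group_by(.data$city_id, .data$date) %>%
    summarise(si = 100 * mean(.data$std), .groups = "drop") %>%
    arrange(.data$city_id, .data$date)
}

#' Standardized trajectory of a single policy indicator
#'
#' Extracts one indicator and standardizes it elementwise to `[0, 1]`: 0
#' when the policy is not implemented, 1 at its maximum level.
#'
#' @inheritParams compute_si
#' @param indicator_id One of `"C1"`..`"C8"`, `"H1"`.
#' @return A tibble with columns `city_id`, `date`, `z`.
#' @export
standardize_policy_variable <- function(panel, indicator_id) {
  ids <- si_indicators()$indicator_id
  if (length(indicator_id) != 1 || !indicator_id %in% ids) {
    abort(paste0(
      "`indicator_id` must be one of ", paste(ids, collapse = ", ")
    ))
  }
  validate_policy_panel(panel)
  panel %>%
    filter(.data$indicator_id == !!indicator_id) %>%
    mutate(z = standardize_indicator(.data$level, .data$max_level)) %>%
    select("city_id", "date", "z") %>%
    arrange(.data$city_id, .data$date)
}

#' Read and validate a policy panel from CSV
#'
#' Expects the long format written by [write_policy_panel()]: columns
#' `city_id`, `date` (ISO-8601), `indicator_id`, `level`, `max_level`.
#' Validation failures (duplicates, levels above maxima, missing
#' indicators) are hard errors naming the offending rows; missing policy
#' data is never imputed.
#'
#' @param path Path to a CSV file.
#' @return A validated policy-panel tibble.
#' @export
read_policy_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(panel) == 0) abort("Policy panel file is empty.")
  panel <- as_tibble(panel) %>%
    mutate(
      date = as.Date(.data$date),
      level = as.integer(.data$level),
      max_level = as.integer(.data$max_level)
    )
  validate_policy_panel(panel)
  panel
}

#' @rdname read_policy_panel
#' @param panel A policy panel.
#' @export
write_policy_panel <- function(panel, path) {
  validate_policy_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
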