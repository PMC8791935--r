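#' Natural-spline specification for the stringency exposure-response
#'
#' The non-linear effect of the Stringency Index is expanded through a
#' natural cubic spline with four degrees of freedom: three interior knots
#' at the 25, 50 and 75% quantiles of the pooled SI distribution (all
#' city-days), boundary knots at 0 and the maximum observed SI, and linear
#' extrapolation beyond the boundary. The basis is anchored at SI = 0
#' (each basis column is shifted by its value at 0), which operationalizes
#' the removed model intercept: no policy response implies no pollutant
#' change.
#'
#' @param si_values Pooled SI values (percent) from which knots are placed.
#' @param df Degrees of freedom; fixed at 4.
#' @param boundary Boundary knots; default `c(0, max(si_values))`.
#' @param anchored_at_zero Shift the basis so every column is 0 at SI = 0.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(si_values, df = 4, boundary = NULL,
                        anchored_at_zero = TRUE) {
  si_values <- si_values[is.finite(si_values)]
  if (length(unique(si_values)) < 5) {
    abort("Need at least 5 distinct SI values to place spline knots.")
  }
  if (df != 4) abort("The exposure-response spline uses df = 4.")
  if (is.null(boundary)) boundary <- c(0, max(si_values))
  knots <- unname(quantile(si_values, c(0.25, 0.5, 0.75), type = 7))
  degenerate <- function(k) {
    any(diff(k) <= 0) || k[1] <= boundary[1] || k[3] >= boundary[2]
  }
  if (degenerate(knots)) {
    # the pooled SI distribution piles up at 0 during the no-response
    # weeks and at the plateau level during lockdown; when a quantile
    # collides with a boundary or another knot, fall back to quantiles of
    # the interior values, then to equally spaced knots
    interior <- si_values[si_values > boundary[1] & si_values < boundary[2]]
    if (length(unique(interior)) >= 5) {
      knots <- unname(quantile(interior, c(0.25, 0.5, 0.75), type = 7))
    }
    if (degenerate(knots)) {
      knots <- boundary[1] + (1:3) / 4 * (boundary[2] - boundary[1])
    }
  }
  if (degenerate(knots)) {
    abort(paste0(
      "Interior knots must be strictly increasing and inside the boundary; ",
      "got knots (", paste(signif(knots, 4), collapse = ", "),
      ") with boundary [", boundary[1], ", ", boundary[2], "]."
    ))
  }
  structure(
    list(
      degrees_of_freedom = 4L, interior_knots = knots,
      boundary = boundary, anchored_at_zero = anchored_at_zero
    ),
    class = "spline_spec"
  )
}

#' Evaluate the anchored natural-spline basis
#'
#' @param si_values SI values (percent) at which to evaluate.
#' @param spec A [spline_spec()].
#' @param warn_extrapolation Warn when values fall outside the boundary
#'   (evaluation still proceeds, linearly).
#' @return An `n x 4` basis matrix; the row at SI = 0 is exactly zero when
#'   the spec is anchored.
#' @export
build_spline_basis <- function(si_values, spec, warn_extrapolation = TRUE) {
  stopifnot(inherits(spec, "spline_spec"))
  if (warn_extrapolation &&
      any(si_values < spec$boundary[1] - 1e-8 |
          si_values > spec$boundary[2] + 1e-8)) {
    warn("SI values outside the spline boundary; extrapolating linearly.")
  }
  b <- splines::ns(
    si_values,
    knots = spec$interior_knots, Boundary.knots = spec$boundary
  )
  b <- unname(b[, , drop = FALSE])
  if (spec$anchored_at_zero) {
    b0 <- splines::ns(
      0, knots = spec$interior_knots, Boundary.knots = spec$boundary
    )
    b <- sweep(b, 2, as.numeric(b0))
  }
  b
}
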