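#' Great-circle distance matrix between cities
#'
#' @param coords A data frame with columns `lon`, `lat` in decimal degrees.
#' @return Symmetric matrix of haversine distances in km.
#' @export
haversine_km <- function(coords) {
  m <- as.matrix(coords[, c("lon", "lat")])
  if (any(!is.finite(m))) abort("Non-finite coordinates.")
  d <- geosphere::distm(m, fun = geosphere::distHaversine) / 1000
  dimnames(d) <- NULL
  d
}

#' Matern covariance over great-circle distances
#'
#' Stationary Matern covariance
#' \deqn{C(d) = \sigma^2 \frac{(\kappa d)^\nu K_\nu(\kappa d)}{2^{\nu-1}\Gamma(\nu)},
#'   \qquad \kappa = \sqrt{8\nu}/\rho,}
#' parameterized by the spatial range \eqn{\rho} (km, the distance at which
#' correlation has dropped to about 0.13), marginal standard deviation
#' \eqn{\sigma}, and smoothness \eqn{\nu}. `C(0)` equals `sd^2`.
#'
#' @param coords Data frame with `lon`, `lat` columns, or a precomputed
#'   distance matrix in km.
#' @param range_km Spatial range \eqn{\rho > 0} in km.
#' @param marginal_sd Marginal standard deviation \eqn{\sigma \ge 0}.
#' @param nu Smoothness \eqn{\nu > 0}; default 1, the 2-D default of
#'   SPDE-based toolchains.
#' @param jitter Diagonal jitter, as a multiple of `sd^2`, to keep the
#'   matrix numerically positive definite. Default `1e-8`.
#' @return An n x n covariance matrix.
#' @export
#' @examples
#' co <- data.frame(lon = c(0, 1), lat = c(50, 50))
#' matern_cov(co, range_km = 200, marginal_sd = 1)
matern_cov <- function(coords, range_km, marginal_sd, nu = 1, jitter = 1e-8) {
  if (range_km <= 0) abort("`range_km` must be > 0.")
  if (marginal_sd < 0) abort("`marginal_sd` must be >= 0.")
  if (nu <= 0) abort("`nu` must be > 0.")
  d <- if (is.matrix(coords)) coords else haversine_km(coords)
  if (any(!is.finite(d))) abort("Non-finite distances.")
  kappa <- sqrt(8 * nu) / range_km
  u <- kappa * d
  corr <- matrix(1, nrow(d), ncol(d))
  pos <- u > 0
  corr[pos] <- (u[pos]^nu) * besselK(u[pos], nu) / (2^(nu - 1) * gamma(nu))
  cov <- marginal_sd^2 * corr
  diag(cov) <- diag(cov) + jitter * marginal_sd^2
  cov
}

#' Penalized-complexity prior for Matern hyperparameters
#'
#' Joint PC prior for the range and marginal standard deviation of a 2-D
#' Matern field, defined by its tail probabilities: `P(range < range0) =
#' alpha_range` and `P(sd > sd0) = alpha_sd`. The range has density
#' \eqn{\pi(\rho) = \lambda_1 \rho^{-2} e^{-\lambda_1/\rho}} with
#' \eqn{\lambda_1 = -\rho_0 \log\alpha_\rho}; the standard deviation is
#' exponential with rate \eqn{\lambda_2 = -\log(\alpha_\sigma)/\sigma_0};
#' the two are independent.
#'
#' @param range0,alpha_range Range threshold (km) and its lower-tail
#'   probability.
#' @param sd0,alpha_sd Standard-deviation threshold and its upper-tail
#'   probability.
#' @return An object of class `pc_prior`.
#' @export
pc_prior <- function(range0 = 500, alpha_range = 0.5, sd0 = 1, alpha_sd = 0.05) {
  stopifnot(
    range0 > 0, sd0 > 0,
    alpha_range > 0, alpha_range < 1, alpha_sd > 0, alpha_sd < 1
  )
  structure(
    list(
      range0 = range0, alpha_range = alpha_range,
      sd0 = sd0, alpha_sd = alpha_sd,
      lambda_range = -range0 * log(alpha_range),
      lambda_sd = -log(alpha_sd) / sd0
    ),
    class = "pc_prior"
  )
}

#' @rdname pc_prior
#' @param range_km,marginal_sd Points at which to evaluate the log-density.
#' @param prior A `pc_prior` object.
#' @return `pc_prior_logdensity()`: the joint log-density, vectorized.
#' @export
pc_prior_logdensity <- function(range_km, marginal_sd, prior) {
  stopifnot(inherits(prior, "pc_prior"))
  out <- rep(-Inf, max(length(range_km), length(marginal_sd)))
  range_km <- rep_len(range_km, length(out))
  marginal_sd <- rep_len(marginal_sd, length(out))
  ok <- range_km > 0 & marginal_sd >= 0
  l1 <- prior$lambda_range
  l2 <- prior$lambda_sd
  out[ok] <- log(l1) - 2 * log(range_km[ok]) - l1 / range_km[ok] +
    log(l2) - l2 * marginal_sd[ok]
  out
}

#' Draw spatially correlated city-level coefficient fields
#'
#' Each column is an independent zero-mean Gaussian draw whose covariance
#' across cities is Matern over great-circle distances; used to generate
#' the city-specific spline deviations of the synthetic data.
#'
#' @param cities A city table with `lon`, `lat` columns.
#' @param range_km,sd,nu Matern parameters (see [matern_cov()]).
#' @param n_fields Number of independent fields (columns).
#' @param seed Integer seed.
#' @return An `n_cities x n_fields` numeric matrix.
#' @export
sample_city_deviations <- function(cities, range_km, sd, nu = 1, n_fields = 4,
                                   seed = 1) {
  n <- nrow(cities)
  if (sd == 0) return(matrix(0, n, n_fields))
  cov <- matern_cov(cities, range_km, sd, nu)
  L <- tryCatch(
    chol(cov),
    error = function(e) abort(
      "Matern covariance is not positive definite even after jitter."
    )
  )
  z <- with_seed(seed, matrix(rnorm(n * n_fields), n, n_fields))
  t(L) %*% z
}
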