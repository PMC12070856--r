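#' Spatial correlation models for annual anomalies
#'
#' Correlation between cells separated by distance `d` under the spherical
#' or exponential family. The sill is the between-cell correlation at zero
#' distance (the nugget complement); the marginal variance of each cell's
#' anomaly is always 1 before scaling.
#'
#' @param family `"spherical"` or `"exponential"`.
#' @param range_km Correlation range, km. Under the spherical model the
#'   correlation is exactly 0 at and beyond this distance.
#' @param sill Correlation at vanishing distance between *distinct* cells,
#'   in \[0, 1\].
#' @return A `spatial_corr_model` list.
#' @export
spatial_corr_model <- function(family = c("spherical", "exponential"),
                               range_km, sill) {
  family <- match.arg(family)
  stopifnot(range_km > 0, sill >= 0, sill <= 1)
  structure(list(family = family, range_km = range_km, sill = sill),
            class = "spatial_corr_model")
}

# Correlation at distance d (km) between distinct cells.
corr_at_distance <- function(model, d) {
  u <- d / model$range_km
  rho <- switch(model$family,
    spherical   = ifelse(u < 1, 1 - 1.5 * u + 0.5 * u^3, 0),
    exponential = exp(-u)
  )
  model$sill * rho
}

#' Temporal structure of annual anomalies
#'
#' @param ar1_coef Lag-1 autoregressive coefficient in (-1, 1) applied to
#'   each cell's anomaly series (innovations carry the spatial correlation,
#'   so the cross-cell correlation of the stationary series equals the
#'   innovation correlation).
#' @param sine_period_years,sine_amplitude A common (spatially uniform)
#'   sinusoidal forcing added to every cell, giving the anomalies a
#'   controllable periodicity; amplitude 0 disables it.
#' @return A `temporal_model` list.
#' @export
temporal_model <- function(ar1_coef = 0, sine_period_years = 4,
                           sine_amplitude = 0) {
  stopifnot(abs(ar1_coef) < 1, sine_period_years > 0, sine_amplitude >= 0)
  structure(list(ar1_coef = ar1_coef, sine_period_years = sine_period_years,
                 sine_amplitude = sine_amplitude), class = "temporal_model")
}

#' Simulate known spatio-temporal rate anomaly fields
#'
#' Draws zero-mean Gaussian-process anomalies for productivity, survival and
#' abundance on the grid cells of a layout. At each year the cross-cell
#' innovation is multivariate normal with the stated spatial correlation
#' (Cholesky factorisation with 1e-10 diagonal jitter); each cell's series
#' then follows a stationary AR(1) with that innovation, plus an optional
#' common sinusoid and a linear trend. The three metrics are independent
#' replicates of the same structure.
#'
#' @param layout A `grid_layout`.
#' @param years Number of years (>= 10) or an integer vector of years.
#' @param spatial A [spatial_corr_model()].
#' @param temporal A [temporal_model()].
#' @param trend_slopes Named numeric, per-year linear trend added to each
#'   metric's anomalies (names among productivity, survival, abundance).
#' @param anomaly_sd Marginal standard deviation of the (unit-variance)
#'   anomaly process on the link scale, per metric (recycled).
#' @param seed Integer seed; all draws flow from one generator.
#' @return A `rate_field`: list with `years`, `cell_ids`, and one
#'   year-by-cell matrix per metric (`productivity_anomaly`,
#'   `survival_anomaly`, `abundance_anomaly`), plus the models used.
#' @export
simulate_rate_field <- function(layout, years, spatial, temporal = temporal_model(),
                                trend_slopes = c(productivity = 0, survival = 0,
                                                 abundance = 0),
                                anomaly_sd = 0.25, seed = 1) {
  stopifnot(inherits(layout, "grid_layout"), inherits(spatial, "spatial_corr_model"))
  if (length(years) == 1) years <- seq_len(years) + 1997L
  ny <- length(years)
  if (ny < 10) stop("need at least 10 years")
  cells <- layout$cells
  nc <- nrow(cells)
  d <- cell_distance_matrix(cells)
  sigma <- corr_at_distance(spatial, d)
  diag(sigma) <- 1
  L <- tryCatch(
    chol(sigma + diag(1e-10, nc)),
    error = function(e) stop("spatial covariance is not positive semi-definite: ",
                             conditionMessage(e))
  )
  metrics <- c("productivity", "survival", "abundance")
  anomaly_sd <- rep_len(anomaly_sd, 3)
  names(anomaly_sd) <- metrics
  slopes <- setNames(rep(0, 3), metrics)
  slopes[names(trend_slopes)] <- trend_slopes
  a1 <- temporal$ar1_coef
  sine <- temporal$sine_amplitude *
    sin(2 * pi * seq_len(ny) / temporal$sine_period_years)
  tc <- seq_len(ny) - (ny + 1) / 2
  set.seed(seed)
  out <- list(years = years, cell_ids = cells$cell_id, spatial = spatial,
              temporal = temporal, trend_slopes = slopes,
              anomaly_sd = anomaly_sd, seed = seed)
  for (m in metrics) {
    z <- matrix(0, ny, nc, dimnames = list(years, cells$cell_id))
    innov <- matrix(rnorm(ny * nc), ny, nc) %*% L
    z[1, ] <- innov[1, ]
    if (ny > 1) {
      w <- sqrt(1 - a1^2)
      for (t in 2:ny) z[t, ] <- a1 * z[t - 1, ] + w * innov[t, ]
    }
    z <- anomaly_sd[[m]] * z + sine + outer(tc * slopes[[m]], rep(1, nc))
    out[[paste0(m, "_anomaly")]] <- z
  }
  structure(out, class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat("rate_field:", length(x$years), "years x", length(x$cell_ids),
      "cells;", x$spatial$family, "correlation, range",
      x$spatial$range_km, "km, sill", x$spatial$sill, "\n")
  invisible(x)
}
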