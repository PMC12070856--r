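#' Detrend annual series
#'
#' Removes a straight-line trend in year from each cell-by-metric series by
#' ordinary least squares (a Gaussian GLM with year as a continuous
#' covariate); the residuals are the detrended series used for all pairwise
#' correlations. Missing years stay missing. Series with fewer than 3
#' non-missing years are excluded and logged.
#'
#' @param series An `annual_series` data frame (any number of cells and
#'   metrics stacked).
#' @return List with `residuals` (data frame `cell_id`, `metric`, `year`,
#'   `residual`) and `exclusions` (cell/metric dropped, with reason).
#' @export
detrend_series <- function(series) {
  keep <- !is.na(series$estimate)
  series <- series[keep, ]
  sp <- split(series, interaction(series$cell_id, series$metric, drop = TRUE))
  res <- list()
  excl <- list()
  for (sub in sp) {
    if (nrow(sub) < 3) {
      excl[[length(excl) + 1L]] <- data.frame(
        cell_id = sub$cell_id[1], metric = sub$metric[1],
        reason = "fewer than 3 years")
      next
    }
    r <- residuals(lm(estimate ~ year, data = sub))
    res[[length(res) + 1L]] <- data.frame(
      cell_id = sub$cell_id, metric = sub$metric, year = sub$year,
      residual = as.numeric(r))
  }
  list(
    residuals = if (length(res)) do.call(rbind, res) else
      data.frame(cell_id = character(), metric = character(),
                 year = integer(), residual = double()),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(cell_id = character(), metric = character(),
                 reason = character())
  )
}

# year x cell residual matrix for one metric
residual_matrix <- function(residuals, metric) {
  sub <- residuals[residuals$metric == metric, ]
  if (!nrow(sub)) return(NULL)
  yrs <- sort(unique(sub$year))
  cells <- sort(unique(sub$cell_id))
  m <- matrix(NA_real_, length(yrs), length(cells),
              dimnames = list(yrs, cells))
  m[cbind(match(sub$year, yrs), match(sub$cell_id, cells))] <- sub$residual
  m
}

#' Pairwise cross-cell correlations of detrended series
#'
#' Pearson correlations between the detrended series of every pair of grid
#' cells whose series overlap by at least `min_overlap` years (self-pairs
#' excluded). For within-metric synchrony (`metric_a == metric_b`, lag 0)
#' unordered pairs are used. For count-rate congruence the count series of
#' the focal cell is lagged one year — count in year t+1 against the rate
#' in year t — and all ordered pairs (focal count cell, other rate cell)
#' are formed. Distances are great-circle between cell centroids.
#'
#' @param residuals Detrended residual data frame from [detrend_series()].
#' @param cells Cell centroid data frame (or `grid_layout`).
#' @param metric_a,metric_b Metric of the focal and other series.
#' @param lag 0 for same-metric synchrony; 1 lags `metric_a` (count)
#'   forward so year t+1 of `metric_a` aligns with year t of `metric_b`.
#' @param min_overlap Minimum overlapping years (default 5).
#' @return List with `pairs` (data frame `cell_a`, `cell_b`, `metric_a`,
#'   `metric_b`, `lag_years`, `distance_km`, `r`, `n_overlap`) and
#'   `skipped` (zero-variance or short overlaps, with reason).
#' @export
pairwise_correlations <- function(residuals, cells, metric_a,
                                  metric_b = metric_a, lag = 0,
                                  min_overlap = 5) {
  if (inherits(cells, "grid_layout")) cells <- cells$cells
  stopifnot(lag %in% c(0, 1))
  if (metric_a == metric_b && lag != 0) stop("same-metric pairs use lag 0")
  ma <- residual_matrix(residuals, metric_a)
  mb <- residual_matrix(residuals, metric_b)
  if (is.null(ma) || is.null(mb)) stop("no residuals for requested metrics")
  if (lag == 1) {
    # align metric_a at year t+1 with metric_b at year t
    rownames(ma) <- as.character(as.integer(rownames(ma)) - 1L)
  }
  same <- metric_a == metric_b
  ca <- colnames(ma)
  cb <- colnames(mb)
  yrs <- intersect(rownames(ma), rownames(mb))
  ma <- ma[yrs, , drop = FALSE]
  mb <- mb[yrs, , drop = FALSE]
  out <- list()
  skipped <- list()
  for (a in ca) {
    others <- if (same) cb[cb > a] else setdiff(cb, a)
    for (b in others) {
      ok <- !is.na(ma[, a]) & !is.na(mb[, b])
      n <- sum(ok)
      if (n < min_overlap) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          cell_a = a, cell_b = b, reason = sprintf("overlap %d < %d", n,
                                                   min_overlap))
        next
      }
      xa <- ma[ok, a]
      xb <- mb[ok, b]
      if (sd(xa) == 0 || sd(xb) == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          cell_a = a, cell_b = b, reason = "zero variance in overlap")
        next
      }
      ia <- match(a, cells$cell_id)
      ib <- match(b, cells$cell_id)
      out[[length(out) + 1L]] <- data.frame(
        cell_a = a, cell_b = b, metric_a = metric_a, metric_b = metric_b,
        lag_years = lag,
        distance_km = haversine_km(cells$centroid_lat[ia], cells$centroid_lon[ia],
                                   cells$centroid_lat[ib], cells$centroid_lon[ib]),
        r = cor(xa, xb), n_overlap = n)
    }
  }
  list(
    pairs = if (length(out)) do.call(rbind, out) else
      data.frame(cell_a = character(), cell_b = character(),
                 metric_a = character(), metric_b = character(),
                 lag_years = integer(), distance_km = double(), r = double(),
                 n_overlap = integer()),
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(cell_a = character(), cell_b = character(),
                 reason = character())
  )
}

#' Fit a spline correlogram to pairwise correlations
#'
#' Models the pairwise correlation coefficients as a cubic regression
#' spline of inter-cell distance (mgcv GAM), and extracts the mean curve
#' with a 95% band by posterior simulation from the approximate
#' multivariate-normal posterior of the spline coefficients. By default
#' the spline uses a fixed `sqrt(n_pairs)` degrees of freedom, the
#' convention of the spline spatial correlogram literature: data-driven
#' smoothing (REML/GCV, also available) systematically over-smooths the
#' zero crossing when the true correlation approaches zero tangentially,
#' biasing the estimated scale of synchrony upward. Following the
#' 20-coefficient rule, no correlogram is fitted with fewer than
#' `min_pairs` correlations.
#'
#' @param pairs Pair data frame from [pairwise_correlations()].
#' @param n_posterior_sims Coefficient draws for the band (default 1000).
#' @param min_pairs Minimum correlations required (default 20).
#' @param grid_step Prediction grid step in km (default 1).
#' @param smoothing `"fixed_df"` (default; regression spline with
#'   `df` degrees of freedom), `"REML"` or `"GCV.Cp"` (penalized).
#' @param df Spline degrees of freedom for `"fixed_df"` (default
#'   `sqrt(n_pairs)`); basis dimension for the penalized methods. Always
#'   reduced when there are few distinct distances.
#' @param seed Seed for the posterior draws.
#' @return A `correlogram`: list with `distance_km`, `fit` (mean curve),
#'   `lower`, `upper`, `se` (pointwise sd of simulated curves), `n_pairs`,
#'   and the `gam` object. Returns `NULL` (with a message) when
#'   `nrow(pairs) < min_pairs`.
#' @export
fit_correlogram <- function(pairs, n_posterior_sims = 1000, min_pairs = 20,
                            grid_step = 1,
                            smoothing = c("fixed_df", "REML", "GCV.Cp"),
                            df = NULL, seed = 1) {
  smoothing <- match.arg(smoothing)
  n <- nrow(pairs)
  if (n < min_pairs) {
    message("correlogram refused: ", n, " pairs < ", min_pairs)
    return(NULL)
  }
  if (is.null(df)) df <- if (smoothing == "fixed_df") ceiling(sqrt(n)) else 20
  k <- min(df, length(unique(pairs$distance_km)) - 1)
  if (k < 3) stop("too few distinct distances for a spline")
  g <- if (smoothing == "fixed_df") {
    mgcv::gam(r ~ s(distance_km, bs = "cr", k = k, fx = TRUE), data = pairs)
  } else {
    mgcv::gam(r ~ s(distance_km, bs = "cr", k = k), data = pairs,
              method = smoothing)
  }
  grid <- seq(0, max(pairs$distance_km), by = grid_step)
  X <- predict(g, newdata = data.frame(distance_km = grid), type = "lpmatrix")
  set.seed(seed)
  beta <- MASS::mvrnorm(n_posterior_sims, coef(g), vcov(g))
  sims <- X %*% t(beta)
  structure(list(
    distance_km = grid,
    fit = as.numeric(X %*% coef(g)),
    lower = apply(sims, 1, quantile, 0.025),
    upper = apply(sims, 1, quantile, 0.975),
    se = apply(sims, 1, sd),
    n_pairs = n, gam = g
  ), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("correlogram over", length(x$distance_km), "km grid points from",
      x$n_pairs, "pairs; strength at d=0:", round(x$fit[1], 3), "\n")
  invisible(x)
}

#' Scale, relative scale and strength of synchrony from a correlogram
#'
#' Strength is the mean curve at distance zero. Scale is the smallest
#' distance at which the mean curve first reaches zero (linear
#' interpolation between grid points); when the curve never reaches zero
#' within the prediction grid the scale is set to the species' minimum
#' distance, and any scale above the minimum distance is capped at it, so
#' relative scale = scale / minimum distance lies in \[0, 1\]. The
#' precision weights follow the resolution-comparison weighting scheme:
#' the scale weight is the inverse of the mean posterior-simulation SE of
#' the predictions between distance 0 and the scale, and the strength
#' weight is the inverse of the width of the 95% band at distance 0.
#'
#' @param cg A `correlogram`.
#' @param minimum_distance_km The species' minimum distance (see
#'   [minimum_distance()]).
#' @return A `synchrony_estimate`: one-row data frame with `scale_km`,
#'   `minimum_distance_km`, `relative_scale`, `strength`, `weight_scale`,
#'   `weight_strength`, `flag`.
#' @export
extract_scale_strength <- function(cg, minimum_distance_km) {
  stopifnot(inherits(cg, "correlogram"), minimum_distance_km > 0)
  y <- cg$fit
  d <- cg$distance_km
  strength <- y[1]
  flag <- ""
  below <- which(y <= 0)
  if (length(below) == 0) {
    scale <- minimum_distance_km
  } else if (below[1] == 1) {
    scale <- 0
    flag <- "curve_nonpositive_at_zero"
  } else {
    i <- below[1]
    # linear interpolation for the crossing between grid points i-1 and i
    scale <- d[i - 1] + (d[i] - d[i - 1]) * y[i - 1] / (y[i - 1] - y[i])
  }
  scale <- min(scale, minimum_distance_km)
  in_range <- d <= scale
  if (!any(in_range)) in_range <- 1L
  w_scale <- 1 / mean(cg$se[in_range])
  w_strength <- 1 / (cg$upper[1] - cg$lower[1])
  structure(
    data.frame(scale_km = scale, minimum_distance_km = minimum_distance_km,
               relative_scale = scale / minimum_distance_km,
               strength = strength, weight_scale = w_scale,
               weight_strength = w_strength, flag = flag),
    class = c("synchrony_estimate", "data.frame")
  )
}
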