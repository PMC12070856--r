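#' Standardise a series for wavelet analysis
#'
#' Linear detrend and de-mean (the "clev 2" cleaning level): ordinary
#' least-squares residuals about a straight line in time, which are
#' mean-zero by construction. Requires at least 8 years and no internal
#' gaps; gapped series should be excluded upstream.
#'
#' @param values Numeric vector of annual estimates.
#' @param years Optional year labels; must be consecutive if supplied.
#' @return Numeric vector of cleaned values.
#' @export
clean_series <- function(values, years = NULL) {
  if (!is.null(years)) {
    if (any(diff(years) != 1)) stop("series has internal gaps")
  }
  if (length(values) < 8) stop("need at least 8 years")
  if (anyNA(values)) stop("series has missing values (gapped cells are excluded)")
  t <- seq_along(values)
  as.numeric(residuals(lm(values ~ t)))
}

#' Geometric timescale grid
#'
#' Timescales from `min_ts` to `T/2` years with successive ratio `ratio`
#' (default 1.05).
#'
#' @param n_years Series length T.
#' @param min_ts Shortest timescale (default 2 years).
#' @param ratio Geometric spacing factor.
#' @return Numeric vector of timescales (years).
#' @export
timescale_grid <- function(n_years, min_ts = 2, ratio = 1.05) {
  smax <- n_years / 2
  if (smax < min_ts) stop("series too short for the timescale grid")
  min_ts * ratio^(0:floor(log(smax / min_ts) / log(ratio) + 1e-9))
}

#' Continuous Morlet wavelet transform
#'
#' Complex Morlet transform with central frequency parameter 1 (so the
#' wavelet at timescale s is tuned to period s years), evaluated by direct
#' convolution at each year. Entries within one e-folding time
#' (sqrt(2) * s) of either end of the series are outside the cone of
#' influence.
#'
#' @param x Cleaned numeric series (see [clean_series()]).
#' @param timescales Timescales in years, each in \[2, T/2\].
#' @return List with `W` (years x timescales complex matrix), `in_cone`
#'   (logical matrix), `timescales`.
#' @export
morlet_cwt <- function(x, timescales) {
  T <- length(x)
  if (any(timescales < 2 - 1e-9 | timescales > T / 2 + 1e-9)) {
    stop("timescales must lie in [2, T/2]")
  }
  u <- seq_len(T)
  W <- matrix(NA_complex_, T, length(timescales))
  in_cone <- matrix(FALSE, T, length(timescales))
  for (j in seq_along(timescales)) {
    s <- timescales[j]
    eta <- outer(u, u, function(uu, tt) (uu - tt) / s) # rows: u, cols: t
    psi <- pi^(-0.25) * exp(-eta^2 / 2) * exp(2i * pi * eta)
    W[, j] <- as.vector(crossprod(Conj(psi), x)) / sqrt(s)
    ef <- sqrt(2) * s
    in_cone[, j] <- (u - 1) >= ef & (T - u) >= ef
  }
  list(W = W, in_cone = in_cone, timescales = timescales)
}

#' Wavelet phasor mean field
#'
#' At each year and timescale every cell's wavelet coefficient is
#' normalised to a unit phasor (coefficient / modulus); the field is the
#' modulus of the across-cell mean of these phasors — 1 under perfect
#' phase synchrony and small under random phases. Cells with zero modulus
#' at a point drop out of that point's mean; points with fewer than 2
#' contributing cells, or outside the cone of influence, are missing.
#'
#' @param transforms List of [morlet_cwt()] results on a shared year and
#'   timescale grid (>= 2 cells).
#' @param years Optional year labels for the output.
#' @param alpha Significance level for the random-phase null (default
#'   0.05).
#' @param n_draws,seed Monte-Carlo settings for [wpmf_threshold()].
#' @return A `wpmf_field`: list with `magnitude` (years x timescales, NA
#'   outside the cone), `timescales`, `years`, `n_cells`, `threshold`.
#' @export
wpmf <- function(transforms, years = NULL, alpha = 0.05, n_draws = 10000,
                 seed = 1) {
  n_cells <- length(transforms)
  if (n_cells < 2) stop("need >= 2 cells")
  dims <- dim(transforms[[1]]$W)
  phasor_sum <- matrix(0 + 0i, dims[1], dims[2])
  contrib <- matrix(0L, dims[1], dims[2])
  for (tr in transforms) {
    stopifnot(all(dim(tr$W) == dims))
    mod <- Mod(tr$W)
    ok <- mod > 0
    z <- matrix(0 + 0i, dims[1], dims[2])
    z[ok] <- tr$W[ok] / mod[ok]
    phasor_sum <- phasor_sum + z
    contrib <- contrib + ok
  }
  mag <- Mod(phasor_sum) / contrib
  mag[contrib < 2] <- NA_real_
  mag[!transforms[[1]]$in_cone] <- NA_real_
  ts <- transforms[[1]]$timescales
  if (is.null(years)) years <- seq_len(dims[1])
  structure(list(
    magnitude = mag, timescales = ts, years = years, n_cells = n_cells,
    threshold = wpmf_threshold(n_cells, alpha = alpha, n_draws = n_draws,
                               seed = seed),
    alpha = alpha
  ), class = "wpmf_field")
}

#' @export
print.wpmf_field <- function(x, ...) {
  cat("wpmf_field:", length(x$years), "years x", length(x$timescales),
      "timescales,", x$n_cells, "cells; threshold",
      round(x$threshold, 3), "(alpha", x$alpha, ")\n")
  invisible(x)
}

#' Random-phase significance threshold for the phasor mean field
#'
#' The (1 - alpha) quantile of the modulus of the mean of `n_cells`
#' independent uniform unit phasors, by seeded Monte-Carlo. For large
#' `n_cells` this approaches the Rayleigh limit sqrt(-log(alpha)/n_cells).
#'
#' @param n_cells Number of cells (>= 2).
#' @param alpha Significance level.
#' @param n_draws Monte-Carlo draws.
#' @param seed Integer seed.
#' @return The threshold in (0, 1\].
#' @export
wpmf_threshold <- function(n_cells, alpha = 0.05, n_draws = 10000, seed = 1) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  th <- matrix(runif(n_draws * n_cells, 0, 2 * pi), n_draws, n_cells)
  mod <- Mod(rowMeans(exp(1i * th)))
  as.numeric(quantile(mod, 1 - alpha))
}

#' Timescale-band significance counts
#'
#' For each timescale band, a year is significant when any in-band
#' timescale at that year has a defined magnitude at or above the field's
#' threshold; the denominator is the number of years with any defined
#' in-band magnitude. Default bands use the closed-open convention
#' \[2, 3\], (3, 5\], (6, T/2\] — short, intermediate and long — leaving
#' (5, 6\] unassigned.
#'
#' @param field A `wpmf_field`.
#' @param bands Named list of `c(lower, upper)`; the short band includes
#'   its lower bound, the others exclude it.
#' @return Data frame with `band`, `n_significant_years`, `n_years`
#'   (bands entirely outside the timescale grid are absent).
#' @export
significant_year_counts <- function(field,
                                    bands = list(short = c(2, 3),
                                                 intermediate = c(3, 5),
                                                 long = c(6, Inf))) {
  ts <- field$timescales
  out <- list()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    inband <- if (nm == names(bands)[1]) ts >= b[1] & ts <= b[2] else
      ts > b[1] & ts <= b[2]
    if (!any(inband)) next
    m <- field$magnitude[, inband, drop = FALSE]
    defined <- rowSums(!is.na(m)) > 0
    sig <- apply(m, 1, function(z) any(!is.na(z) & z >= field$threshold))
    out[[length(out) + 1L]] <- data.frame(
      band = nm, n_significant_years = sum(sig & defined),
      n_years = sum(defined))
  }
  do.call(rbind, out)
}

#' Composite phasor mean field across species
#'
#' Entrywise missing-aware mean of the magnitude matrices of several
#' species' fields, on the intersection of their year and timescale grids.
#'
#' @param fields Non-empty list of `wpmf_field` objects.
#' @return List with `magnitude`, `years`, `timescales`, `n_species`.
#' @export
composite_wpmf <- function(fields) {
  if (!length(fields)) stop("empty group")
  yrs <- Reduce(intersect, lapply(fields, `[[`, "years"))
  tss <- Reduce(intersect, lapply(fields, function(f) round(f$timescales, 9)))
  if (!length(yrs) || !length(tss)) stop("no shared year/timescale grid")
  acc <- matrix(0, length(yrs), length(tss))
  cnt <- matrix(0L, length(yrs), length(tss))
  for (f in fields) {
    m <- f$magnitude[match(yrs, f$years),
                     match(tss, round(f$timescales, 9)), drop = FALSE]
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  mag <- acc / cnt
  mag[cnt == 0L] <- NA_real_
  list(magnitude = mag, years = yrs, timescales = tss,
       n_species = length(fields))
}
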